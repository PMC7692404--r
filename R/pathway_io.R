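#' Read a normalized expression matrix with sample annotations
#'
#' Parses a tab-separated expression table (first column gene IDs, remaining
#' columns one per sample, header row of sample IDs) together with an
#' annotation table assigning every sample to the \code{normal} or
#' \code{tumor} group. Gene identifiers are treated as opaque, case-sensitive
#' strings; no aliasing or symbol translation is attempted.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the annotation TSV with columns
#'   \code{sample_id}, \code{group} (values \code{normal} or \code{tumor}),
#'   and optionally \code{subtype}.
#' @param cohort_label Free-text label carried through outputs (e.g. a
#'   cancer-type code).
#' @param log_transformed Set \code{TRUE} if the values were log-transformed
#'   upstream, in which case negative entries are permitted.
#'
#' @return An object of class \code{expr_matrix}: a list with \code{values}
#'   (numeric genes x samples matrix with dimnames), \code{sample_group}
#'   (named character vector), \code{subtype} (named character vector or
#'   \code{NULL}), \code{cohort_label} and \code{log_transformed}.
#' @export
read_expression <- function(path, annotation_path, cohort_label = "cohort",
                            log_transformed = FALSE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("no genes parsed from ", path)
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (length(sample_ids) == 0L) stop("no sample columns in ", path)
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicate sample ID(s) in header: ", paste(unique(dup_s), collapse = ", "))
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop("duplicate gene row(s): ", paste(unique(dup_g), collapse = ", "))
  }

  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  if (!log_transformed && any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop(sprintf(paste0("negative value at gene '%s', sample '%s'; ",
                        "set log_transformed = TRUE if values are on a log scale"),
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)

  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  req <- c("sample_id", "group")
  if (!all(req %in% colnames(ann))) {
    stop("annotation must have columns sample_id and group")
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  missing_ann <- setdiff(sample_ids, ann$sample_id)
  if (length(missing_ann)) {
    stop("sample(s) missing annotation: ", paste(missing_ann, collapse = ", "))
  }
  grp <- ann$group[match(sample_ids, ann$sample_id)]
  if (!all(grp %in% c("normal", "tumor"))) {
    stop("annotation group must be 'normal' or 'tumor'; got: ",
         paste(unique(setdiff(grp, c("normal", "tumor"))), collapse = ", "))
  }
  names(grp) <- sample_ids
  subtype <- NULL
  if ("subtype" %in% colnames(ann)) {
    subtype <- ann$subtype[match(sample_ids, ann$sample_id)]
    names(subtype) <- sample_ids
  }

  structure(list(values = num, sample_group = grp, subtype = subtype,
                 cohort_label = cohort_label,
                 log_transformed = log_transformed),
            class = "expr_matrix")
}

#' Write an expression matrix (and its annotation) back to TSV
#'
#' Inverse of [read_expression()]; values are written with full precision
#' (\code{format(..., digits = 17)} trimmed), so finite decimal inputs
#' round-trip bit-identically.
#'
#' @param x An \code{expr_matrix}.
#' @param path Output expression TSV path.
#' @param annotation_path Optional output annotation TSV path.
#' @return \code{invisible(path)}.
#' @export
write_expression <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values),
                   apply(x$values, 2L, function(col) {
                     sub("^\\s+", "", format(col, digits = 17, trim = TRUE,
                                             scientific = FALSE))
                   }),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = names(x$sample_group),
                      group = unname(x$sample_group),
                      stringsAsFactors = FALSE)
    if (!is.null(x$subtype)) ann$subtype <- unname(x$subtype)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Drop genes with zero expression in more than a fraction of samples
#'
#' Genes whose fraction of exactly-zero values across all samples of the
#' cohort (normal and tumor jointly) strictly exceeds the threshold are
#' removed. A gene with zeros in exactly the threshold fraction is retained.
#'
#' @param x An \code{expr_matrix}.
#' @param zero_fraction_threshold Exclusion threshold in \code{(0, 1]};
#'   default 0.75.
#' @return The filtered \code{expr_matrix}; gene order is preserved.
#' @export
filter_genes <- function(x, zero_fraction_threshold = 0.75) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!(zero_fraction_threshold > 0 && zero_fraction_threshold <= 1)) {
    stop("zero_fraction_threshold must be in (0, 1]")
  }
  zf <- rowMeans(x$values == 0)
  keep <- zf <= zero_fraction_threshold
  if (!any(keep)) stop("all genes removed by the zero-fraction filter")
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' Read a pathway edge list (three-column export dialect)
#'
#' Each line holds a pathway name and the two gene symbols of one undirected
#' edge, tab-separated. Edges with either endpoint outside \code{known_genes},
#' self-loops, and duplicate unordered pairs within a pathway are dropped;
#' pathways left with no edges are removed. A per-pathway account of dropped
#' edges is attached for logging.
#'
#' @param path Path to the three-column TSV (no header).
#' @param known_genes Character vector: the gene universe after filtering.
#' @return An object of class \code{pathway_edges}: a named list of two-column
#'   character matrices (\code{gene_a}, \code{gene_b}), one per pathway, with
#'   attribute \code{dropped} (data.frame pathway/n_dropped).
#' @export
read_pathways <- function(path, known_genes) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no pathway lines parsed from ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    stop("malformed pathway line (expected 3 tab-separated columns) at line ",
         which(nf != 3L)[1L])
  }
  tab <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  pw <- tab[, 1L]; ga <- tab[, 2L]; gb <- tab[, 3L]

  known <- ga %in% known_genes & gb %in% known_genes
  loop <- ga == gb
  keep <- known & !loop

  out <- list()
  dropped <- integer(0)
  for (p in unique(pw)) {
    sel <- pw == p
    a <- ga[sel & keep]; b <- gb[sel & keep]
    # canonical unordered orientation, then dedupe
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    uniq <- !duplicated(key)
    n_drop <- sum(sel) - sum(uniq)
    dropped[p] <- n_drop
    if (any(uniq)) {
      out[[p]] <- cbind(gene_a = lo[uniq], gene_b = hi[uniq])
    }
  }
  if (!length(out)) stop("no pathways retained after filtering")
  structure(out, class = "pathway_edges",
            dropped = data.frame(pathway = names(dropped),
                                 n_dropped = unname(dropped),
                                 stringsAsFactors = FALSE))
}

#' Read a clinical table (sample, survival time, event status)
#'
#' @param path TSV with header columns \code{sample_id}, \code{time} (days,
#'   nonnegative) and \code{event} (1 = death observed, 0 = censored).
#'   Column names \code{time_days} and \code{time} are both accepted.
#' @return A data.frame with columns \code{sample_id}, \code{time},
#'   \code{event}; rows with a missing time or event are dropped with a
#'   message giving the count.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if ("time_days" %in% colnames(df) && !"time" %in% colnames(df)) {
    colnames(df)[colnames(df) == "time_days"] <- "time"
  }
  req <- c("sample_id", "time", "event")
  if (!all(req %in% colnames(df))) {
    stop("clinical table must have columns sample_id, time (or time_days), event")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  suppressWarnings({
    tm <- as.numeric(df$time)
    ev <- as.numeric(df$event)
  })
  incomplete <- is.na(tm) | is.na(ev) | !nzchar(df$time) | !nzchar(df$event)
  if (any(incomplete)) {
    message(sum(incomplete), " clinical row(s) with missing time/event dropped")
    df <- df[!incomplete, , drop = FALSE]
    tm <- tm[!incomplete]; ev <- ev[!incomplete]
  }
  if (!nrow(df)) stop("no complete clinical rows in ", path)
  if (any(tm < 0)) stop("negative survival time for sample ",
                        df$sample_id[which(tm < 0)[1L]])
  if (!all(ev %in% c(0, 1))) {
    stop("event status must be 0 or 1; sample ",
         df$sample_id[which(!ev %in% c(0, 1))[1L]], " has '",
         df$event[which(!ev %in% c(0, 1))[1L]], "'")
  }
  data.frame(sample_id = df$sample_id, time = tm, event = as.integer(ev),
             stringsAsFactors = FALSE)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix '%s': %d genes x %d samples (%d normal, %d tumor)\n",
              x$cohort_label, nrow(x$values), ncol(x$values),
              sum(x$sample_group == "normal"), sum(x$sample_group == "tumor")))
  invisible(x)
}

#' @export
print.pathway_edges <- function(x, ...) {
  m <- vapply(x, nrow, integer(1))
  cat(sprintf("pathway_edges: %d pathways, %d edges (m range %d-%d)\n",
              length(x), sum(m), min(m), max(m)))
  invisible(x)
}

#' Number of retained edges per pathway
#' @param edges A \code{pathway_edges} object.
#' @return Named integer vector of edge counts.
#' @export
pathway_sizes <- function(edges) {
  stopifnot(inherits(edges, "pathway_edges"))
  vapply(edges, nrow, integer(1))
}
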