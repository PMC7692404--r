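# Delta-PCC vector used for scoring one sample: globally-undefined edges stay
# NA (excluded everywhere); a delta that is indeterminate for this sample only
# (e.g. a leave-one-out reference that lost its variance) counts as zero
# perturbation so every sample averages over the same edge set.
.scoring_deltas <- function(reference, sample_values) {
  d <- .augment_all(reference, sample_values) - reference$pcc_n
  d[is.na(d) & reference$defined] <- 0
  d
}

#' Individual-level pathway scores of one sample
#'
#' The iPS of a pathway is the mean absolute delta-PCC over the pathway's
#' retained (defined) edges: the average correlation perturbation the sample
#' induces on the pathway, in [0, 2].
#'
#' @param reference An \code{edge_reference} built from the normal samples.
#' @param sample_values Named numeric vector: the sample's expression.
#' @param min_edges Minimum number of defined edges a pathway needs to be
#'   scored (default 3); pathways below it get \code{NA}.
#' @return Named numeric vector of iPS values, one per pathway (NA where
#'   unscored).
#' @export
ips_for_sample <- function(reference, sample_values, min_edges = 3L) {
  stopifnot(inherits(reference, "edge_reference"))
  d <- abs(.scoring_deltas(reference, sample_values))
  vapply(reference$pathway_index, function(idx) {
    idx <- idx[reference$defined[idx]]
    if (length(idx) < min_edges) NA_real_ else mean(d[idx])
  }, numeric(1))
}

#' iPS matrix over all samples and pathways
#'
#' Scores every sample (tumor and normal) on every pathway. Tumor samples are
#' scored against the full normal reference. Normal samples are scored
#' according to \code{scoring_mode}: with \code{"leave_one_out"} (default)
#' each normal sample is scored against the reference rebuilt without it, via
#' an O(1) downdate of the sufficient statistics, so the normal-sample score
#' distribution is not deflated by self-inclusion; with \code{"pooled"} each
#' normal is scored against the full reference including itself.
#'
#' @param reference An \code{edge_reference} built from the cohort's normal
#'   samples.
#' @param x The \code{expr_matrix} holding all samples to score.
#' @param scoring_mode \code{"leave_one_out"} or \code{"pooled"}; affects
#'   normal samples only.
#' @param min_edges Minimum defined edges per scored pathway (default 3).
#' @return An object of class \code{ips_matrix}: list with \code{scores}
#'   (pathways x samples numeric matrix; NA rows for unscored pathways),
#'   \code{m} (defined-edge count per pathway), \code{sample_group},
#'   \code{scoring_mode}, \code{min_edges}, \code{ref_n}.
#' @export
ips_matrix <- function(reference, x, scoring_mode = c("leave_one_out", "pooled"),
                       min_edges = 3L) {
  scoring_mode <- match.arg(scoring_mode)
  stopifnot(inherits(reference, "edge_reference"), inherits(x, "expr_matrix"))

  pw <- names(reference$pathway_index)
  m <- vapply(reference$pathway_index,
              function(idx) sum(reference$defined[idx]), integer(1))
  unscored <- pw[m < min_edges]
  if (length(unscored)) {
    message(length(unscored), " pathway(s) with fewer than ", min_edges,
            " defined edges left unscored: ",
            paste(utils::head(unscored, 5L), collapse = ", "))
  }

  samples <- colnames(x$values)
  scores <- matrix(NA_real_, nrow = length(pw), ncol = length(samples),
                   dimnames = list(pw, samples))
  is_ref <- samples %in% reference$ref_sample_ids

  for (j in seq_along(samples)) {
    sv <- x$values[, j]
    if (is_ref[j] && scoring_mode == "leave_one_out") {
      loo <- .downdate_reference(reference, sv)
      scores[, j] <- ips_for_sample(loo, sv, min_edges = min_edges)
    } else {
      scores[, j] <- ips_for_sample(reference, sv, min_edges = min_edges)
    }
  }
  if (all(is.na(scores))) {
    stop("no pathway could be scored for any sample")
  }

  structure(list(scores = scores, m = m,
                 sample_group = x$sample_group[samples],
                 scoring_mode = scoring_mode,
                 min_edges = as.integer(min_edges),
                 ref_n = reference$n),
            class = "ips_matrix")
}

#' @export
print.ips_matrix <- function(x, ...) {
  cat(sprintf(paste0("ips_matrix: %d pathways (%d scored) x %d samples; ",
                     "mode = %s, reference n = %d\n"),
              nrow(x$scores), sum(!is.na(rowSums(x$scores))), ncol(x$scores),
              x$scoring_mode, x$ref_n))
  invisible(x)
}

#' Write / read an iPS matrix as TSV plus a JSON metadata sidecar
#'
#' The TSV has pathways as rows and samples as columns; the sidecar records
#' the scoring mode, per-pathway edge counts, sample groups and reference
#' size, so the matrix can be reloaded losslessly for classification.
#'
#' @param ips An \code{ips_matrix}.
#' @param path Output TSV path; the sidecar is written next to it as
#'   \code{<path>.meta.json}.
#' @return \code{invisible(path)}.
#' @export
write_ips_matrix <- function(ips, path) {
  stopifnot(inherits(ips, "ips_matrix"))
  df <- data.frame(pathway = rownames(ips$scores), ips$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(scoring_mode = ips$scoring_mode, min_edges = ips$min_edges,
               ref_n = ips$ref_n,
               m = as.list(ips$m),
               sample_group = as.list(ips$sample_group))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ips_matrix
#' @param path Path of a TSV written by \code{write_ips_matrix}.
#' @return \code{read_ips_matrix}: the reconstructed \code{ips_matrix}.
#' @export
read_ips_matrix <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path)) stop("iPS matrix file not found: ", path)
  if (!file.exists(meta_path)) stop("iPS metadata sidecar not found: ", meta_path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "")
  scores <- as.matrix(df[, -1L, drop = FALSE])
  rownames(scores) <- df[[1L]]
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(scores = scores,
                 m = vapply(meta$m, as.integer, integer(1)),
                 sample_group = vapply(meta$sample_group, as.character,
                                       character(1)),
                 scoring_mode = meta$scoring_mode,
                 min_edges = as.integer(meta$min_edges),
                 ref_n = as.integer(meta$ref_n)),
            class = "ips_matrix")
}
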