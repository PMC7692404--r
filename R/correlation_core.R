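# Pearson correlation from sufficient statistics.
# vx, vy are n*Sxx - Sx^2 style scatter terms; values within rounding of zero
# are treated as zero variance (undefined correlation).
.pcc_from_sums <- function(n, Sx, Sy, Sxx, Syy, Sxy) {
  num <- n * Sxy - Sx * Sy
  vx <- n * Sxx - Sx * Sx
  vy <- n * Syy - Sy * Sy
  tol_x <- 1e-10 * n * pmax(Sxx, .Machine$double.xmin)
  tol_y <- 1e-10 * n * pmax(Syy, .Machine$double.xmin)
  degen <- vx <= tol_x | vy <= tol_y
  r <- rep(NA_real_, length(num))
  ok <- !degen
  r[ok] <- num[ok] / sqrt(vx[ok] * vy[ok])
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  list(pcc = r, degenerate = degen)
}

#' Build per-edge reference statistics over the normal samples
#'
#' For every unique edge appearing in any pathway, accumulates the sufficient
#' statistics (n, sums, cross-products) of its two genes over the reference
#' (normal) samples and derives the reference Pearson correlation PCC_n.
#' Edges where either gene has zero variance across the reference are flagged
#' undefined and excluded from all downstream scoring, for every sample alike,
#' so that each pathway's score always averages over the same edge set.
#'
#' @param x An \code{expr_matrix} (its normal samples are used) or a plain
#'   numeric genes x samples matrix of reference samples.
#' @param edges A \code{pathway_edges} object.
#' @return An object of class \code{edge_reference}: unique-edge table,
#'   per-edge sufficient statistics and \code{pcc_n}, per-pathway indices
#'   into the edge table, reference size \code{n} and sample IDs.
#' @export
build_reference <- function(x, edges) {
  stopifnot(inherits(edges, "pathway_edges"))
  if (inherits(x, "expr_matrix")) {
    ref <- x$values[, x$sample_group == "normal", drop = FALSE]
  } else if (is.matrix(x) && is.numeric(x)) {
    ref <- x
  } else {
    stop("x must be an expr_matrix or a numeric matrix")
  }
  n <- ncol(ref)
  if (n < 3L) stop("at least 3 reference (normal) samples are required; got ", n)
  if (n < 20L) {
    warning("only ", n, " reference samples; the normal baseline may not be ",
            "representative", call. = FALSE)
  }

  all_a <- unlist(lapply(edges, function(e) e[, "gene_a"]), use.names = FALSE)
  all_b <- unlist(lapply(edges, function(e) e[, "gene_b"]), use.names = FALSE)
  missing_g <- setdiff(unique(c(all_a, all_b)), rownames(ref))
  if (length(missing_g)) {
    stop("gene(s) in edge list absent from expression matrix: ",
         paste(utils::head(missing_g, 5L), collapse = ", "))
  }
  key <- paste(all_a, all_b, sep = "\r")
  uniq <- !duplicated(key)
  ea <- all_a[uniq]; eb <- all_b[uniq]
  edge_of <- match(key, key[uniq])
  counts <- lengths(edges)  # rows per pathway via nrow below
  sizes <- vapply(edges, nrow, integer(1))
  pathway_index <- split(edge_of, rep(names(edges), sizes))[names(edges)]

  ia <- match(ea, rownames(ref)); ib <- match(eb, rownames(ref))
  A <- ref[ia, , drop = FALSE]; B <- ref[ib, , drop = FALSE]
  Sx <- rowSums(A);  Sy <- rowSums(B)
  Sxx <- rowSums(A * A); Syy <- rowSums(B * B); Sxy <- rowSums(A * B)
  pc <- .pcc_from_sums(n, Sx, Sy, Sxx, Syy, Sxy)

  structure(list(gene_a = ea, gene_b = eb, n = n,
                 Sx = Sx, Sy = Sy, Sxx = Sxx, Syy = Syy, Sxy = Sxy,
                 pcc_n = pc$pcc, defined = !pc$degenerate,
                 pathway_index = pathway_index,
                 ref_sample_ids = colnames(ref)),
            class = "edge_reference")
}

#' @export
print.edge_reference <- function(x, ...) {
  cat(sprintf("edge_reference: %d unique edges (%d defined), %d pathways, n = %d\n",
              length(x$gene_a), sum(x$defined), length(x$pathway_index), x$n))
  invisible(x)
}

# Extract per-gene expression values for one sample, for edge endpoints.
# sample_values: named numeric vector covering every edge gene.
.edge_sample_values <- function(reference, sample_values) {
  a <- sample_values[reference$gene_a]
  b <- sample_values[reference$gene_b]
  if (anyNA(a) || anyNA(b)) {
    miss <- unique(c(reference$gene_a[is.na(a)], reference$gene_b[is.na(b)]))
    stop("sample is missing expression for edge gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  list(a = as.numeric(a), b = as.numeric(b))
}

# Augmented PCC over all edges at once: O(1) sufficient-statistic update per
# edge. Degenerate augmented variance falls back to PCC_n (delta = 0).
.augment_all <- function(reference, sample_values) {
  v <- .edge_sample_values(reference, sample_values)
  n1 <- reference$n + 1L
  pc <- .pcc_from_sums(n1,
                       reference$Sx + v$a, reference$Sy + v$b,
                       reference$Sxx + v$a^2, reference$Syy + v$b^2,
                       reference$Sxy + v$a * v$b)
  out <- pc$pcc
  out[pc$degenerate] <- reference$pcc_n[pc$degenerate]
  out[!reference$defined] <- NA_real_
  out
}

# Remove one reference sample from the sufficient statistics (O(1) downdate);
# returns an edge_reference over the remaining n - 1 samples. Definedness of
# edges is kept global (from the full reference) for comparability.
.downdate_reference <- function(reference, sample_values) {
  v <- .edge_sample_values(reference, sample_values)
  n0 <- reference$n - 1L
  r <- reference
  r$n <- n0
  r$Sx <- r$Sx - v$a;      r$Sy <- r$Sy - v$b
  r$Sxx <- r$Sxx - v$a^2;  r$Syy <- r$Syy - v$b^2
  r$Sxy <- r$Sxy - v$a * v$b
  pc <- .pcc_from_sums(n0, r$Sx, r$Sy, r$Sxx, r$Syy, r$Sxy)
  # an edge can lose its variance in the reduced panel; its pcc is then
  # undefined for this leave-one-out reference and contributes delta = 0
  pcc <- pc$pcc
  pcc[pc$degenerate] <- NA_real_
  r$pcc_n <- pcc
  r
}

#' Augmented Pearson correlation for one edge and one added sample
#'
#' Computes the correlation of an edge's two genes over the n reference
#' samples plus one added sample, via an O(1) update of the stored sums.
#' If the augmented values have zero variance in either gene, the reference
#' correlation PCC_n is returned (the added sample carries no correlation
#' evidence, so the perturbation is zero).
#'
#' @param reference An \code{edge_reference}.
#' @param edge Character vector of the edge's two gene IDs.
#' @param sample_values Named numeric vector of the added sample's expression.
#' @return The augmented correlation PCC_(n+1), or \code{NA} if the edge is
#'   undefined in the reference.
#' @export
augmented_pcc <- function(reference, edge, sample_values) {
  i <- .edge_index(reference, edge)
  sub <- .subset_reference(reference, i)
  .augment_all(sub, sample_values)
}

#' Single-sample correlation perturbation of one edge
#'
#' \code{delta_pcc} returns PCC_(n+1) - PCC_n: how much adding the one sample
#' changes the edge's correlation relative to the normal reference. Values lie
#' in [-2, 2].
#'
#' @inheritParams augmented_pcc
#' @return The edge's delta-PCC for this sample.
#' @export
delta_pcc <- function(reference, edge, sample_values) {
  i <- .edge_index(reference, edge)
  sub <- .subset_reference(reference, i)
  .augment_all(sub, sample_values) - sub$pcc_n
}

.edge_index <- function(reference, edge) {
  stopifnot(inherits(reference, "edge_reference"), length(edge) == 2L)
  lo <- min(edge); hi <- max(edge)
  i <- which(reference$gene_a == lo & reference$gene_b == hi)
  if (!length(i)) stop("edge not present in reference: ", lo, "-", hi)
  i[1L]
}

.subset_reference <- function(reference, i) {
  r <- reference
  for (f in c("gene_a", "gene_b", "Sx", "Sy", "Sxx", "Syy", "Sxy",
              "pcc_n", "defined")) {
    r[[f]] <- r[[f]][i]
  }
  r$pathway_index <- NULL
  r
}

# All-edge delta-PCC vector for one sample against a given reference.
.delta_all <- function(reference, sample_values) {
  d <- .augment_all(reference, sample_values) - reference$pcc_n
  d[!reference$defined] <- NA_real_
  d
}
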