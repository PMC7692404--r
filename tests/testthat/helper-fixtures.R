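# Shared in-code fixtures: everything is built programmatically.

# expr_matrix from a plain matrix + group vector
make_expr <- function(values, groups, label = "test") {
  structure(list(values = values,
                 sample_group = stats::setNames(groups, colnames(values)),
                 subtype = NULL, cohort_label = label,
                 log_transformed = FALSE),
            class = "expr_matrix")
}

# pathway_edges from a named list of 2-column gene-pair matrices
make_edges <- function(pairs) {
  out <- lapply(pairs, function(m) {
    m <- as.matrix(m)
    cbind(gene_a = pmin(m[, 1L], m[, 2L]), gene_b = pmax(m[, 1L], m[, 2L]))
  })
  class(out) <- "pathway_edges"
  attr(out, "dropped") <- data.frame(pathway = names(out),
                                     n_dropped = 0L,
                                     stringsAsFactors = FALSE)
  out
}

# ips_matrix assembled directly from a score matrix
make_ips <- function(scores, groups, mode = "leave_one_out", m = NULL) {
  if (is.null(m)) m <- stats::setNames(rep(3L, nrow(scores)),
                                       rownames(scores))
  structure(list(scores = scores, m = m,
                 sample_group = stats::setNames(groups, colnames(scores)),
                 scoring_mode = mode, min_edges = 3L,
                 ref_n = sum(groups == "normal")),
            class = "ips_matrix")
}

# the worked three-normal reference: GA/GB for the delta = -1.2 edge,
# GA/GC for the colinear (delta = 0) edge
hand_reference <- function() {
  vals <- rbind(GA = c(1, 2, 3), GB = c(1, 2, 3), GC = c(2, 4, 6))
  colnames(vals) <- paste0("N", 1:3)
  edges <- make_edges(list(PH = rbind(c("GA", "GB"), c("GA", "GC"))))
  suppressWarnings(build_reference(vals, edges))
}

# write a small expression + annotation TSV pair, return the two paths
write_expr_fixture <- function(dir, values, groups) {
  x <- make_expr(values, groups)
  ep <- file.path(dir, "expr.tsv"); ap <- file.path(dir, "ann.tsv")
  write_expression(x, ep, ap)
  c(expression = ep, annotation = ap)
}

# naive Pearson on raw vectors: independent of the sufficient-statistics path
naive_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
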