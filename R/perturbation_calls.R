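#' Per-pathway normal-sample iPS baseline (mean and standard deviation)
#'
#' For each scored pathway, the mean and sample (n-1 denominator) standard
#' deviation of the normal samples' iPS values. These define the null against
#' which tumor samples are judged; pathways with fewer than 3 scored normal
#' samples are left unscored.
#'
#' @param ips An \code{ips_matrix}.
#' @return Data frame with columns \code{pathway}, \code{mu}, \code{sigma},
#'   \code{n_normal} (NA rows where unscored).
#' @export
null_stats <- function(ips) {
  stopifnot(inherits(ips, "ips_matrix"))
  norm <- ips$scores[, ips$sample_group == "normal", drop = FALSE]
  n_ok <- rowSums(!is.na(norm))
  mu <- ifelse(n_ok >= 3L, rowMeans(norm, na.rm = TRUE), NA_real_)
  sigma <- apply(norm, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 3L) stats::sd(v) else NA_real_
  })
  data.frame(pathway = rownames(ips$scores), mu = mu, sigma = sigma,
             n_normal = n_ok, row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify samples as perturbed-strong or perturbed-weak per pathway
#'
#' A sample is perturbed-strong on a pathway when its iPS lies more than
#' \code{k} standard deviations away from the normal samples' mean iPS
#' (strictly; equality at the boundary is weak). The default rule is
#' two-sided distance from the mean; \code{rule = "one_sided"} flags only
#' upward deviations (iPS > mu + k * sigma).
#'
#' @param ips An \code{ips_matrix}.
#' @param null A data frame from [null_stats()].
#' @param k Threshold multiplier (default 2).
#' @param rule \code{"two_sided"} (default) or \code{"one_sided"}.
#' @return An object of class \code{perturbation_calls}: list with
#'   \code{labels} (character matrix pathways x samples with values
#'   \code{"strong"}, \code{"weak"} or NA), the \code{ips} scores, the null
#'   parameters, \code{k}, \code{rule} and \code{sample_group}.
#' @export
classify <- function(ips, null = null_stats(ips), k = 2,
                     rule = c("two_sided", "one_sided")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ips, "ips_matrix"), k > 0)
  if (!identical(null$pathway, rownames(ips$scores))) {
    null <- null[match(rownames(ips$scores), null$pathway), , drop = FALSE]
  }
  dev <- ips$scores - null$mu
  if (rule == "two_sided") dev <- abs(dev)
  # strict "more than k sigma": a relative guard keeps decimal ties (e.g.
  # |0.14 - 0.10| vs 2 * 0.02) on the weak side despite binary rounding
  thr <- k * null$sigma
  strong <- dev - thr > 1e-9 * (abs(dev) + abs(thr))
  labels <- ifelse(strong, "strong", "weak")
  labels[is.na(ips$scores) | is.na(null$mu)] <- NA_character_
  dimnames(labels) <- dimnames(ips$scores)
  structure(list(labels = labels, scores = ips$scores, null = null,
                 k = k, rule = rule, sample_group = ips$sample_group),
            class = "perturbation_calls")
}

#' @export
print.perturbation_calls <- function(x, ...) {
  tum <- x$labels[, x$sample_group == "tumor", drop = FALSE]
  cat(sprintf(paste0("perturbation_calls: %d pathways x %d samples; k = %g ",
                     "(%s); %.1f%% of scored tumor calls strong\n"),
              nrow(x$labels), ncol(x$labels), x$k, x$rule,
              100 * mean(tum == "strong", na.rm = TRUE)))
  invisible(x)
}

#' Percentage of perturbed-strong pathways per tumor sample
#'
#' For each tumor sample, 100 x (number of pathways on which it is
#' perturbed-strong) / (number of pathways scored for it). Unscored pathways
#' are excluded from the denominator.
#'
#' @param calls A \code{perturbation_calls} object.
#' @return Named numeric vector (percent) over tumor samples; samples with no
#'   scored pathway are omitted with a message.
#' @export
fraction_strong_per_sample <- function(calls) {
  stopifnot(inherits(calls, "perturbation_calls"))
  tum <- calls$labels[, calls$sample_group == "tumor", drop = FALSE]
  n_scored <- colSums(!is.na(tum))
  none <- n_scored == 0L
  if (any(none)) {
    message(sum(none), " tumor sample(s) with no scored pathway omitted")
  }
  out <- 100 * colSums(tum == "strong", na.rm = TRUE)[!none] / n_scored[!none]
  out
}

#' Percentage of perturbed-strong tumor samples per pathway
#'
#' For each pathway, 100 x (number of tumor samples called strong) /
#' (number of tumor samples scored on it).
#'
#' @param calls A \code{perturbation_calls} object.
#' @return Named numeric vector (percent) over scored pathways.
#' @export
fraction_strong_per_pathway <- function(calls) {
  stopifnot(inherits(calls, "perturbation_calls"))
  tum <- calls$labels[, calls$sample_group == "tumor", drop = FALSE]
  n_scored <- rowSums(!is.na(tum))
  keep <- n_scored > 0L
  100 * rowSums(tum == "strong", na.rm = TRUE)[keep] / n_scored[keep]
}

#' Write perturbation calls and summary fraction tables
#'
#' Emits a long-format calls TSV (sample, pathway, iPS, mu, sigma, label over
#' tumor samples) and the two summary tables: percent perturbed pathways per
#' patient and percent perturbed patients per pathway.
#'
#' @param calls A \code{perturbation_calls} object.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "perturbation_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tum_ids <- names(calls$sample_group)[calls$sample_group == "tumor"]
  long <- expand.grid(pathway = rownames(calls$labels), sample = tum_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$ips <- calls$scores[cbind(long$pathway, long$sample)]
  nmap <- match(long$pathway, calls$null$pathway)
  long$mu <- calls$null$mu[nmap]
  long$sigma <- calls$null$sigma[nmap]
  long$label <- calls$labels[cbind(long$pathway, long$sample)]
  long <- long[!is.na(long$label), c("sample", "pathway", "ips", "mu",
                                     "sigma", "label")]
  f1 <- file.path(dir, "calls.tsv")
  utils::write.table(long, f1, sep = "\t", quote = FALSE, row.names = FALSE)

  ps <- fraction_strong_per_sample(calls)
  f2 <- file.path(dir, "percent_strong_per_sample.tsv")
  utils::write.table(data.frame(sample = names(ps), percent_strong = ps),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- fraction_strong_per_pathway(calls)
  f3 <- file.path(dir, "percent_strong_per_pathway.tsv")
  utils::write.table(data.frame(pathway = names(pp), percent_strong = pp),
                     f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, f3))
}

#' Read a calls TSV written by [write_calls()] back into a calls object
#'
#' Reconstructs the label and score matrices over tumor samples (normal
#' samples are not part of the long export).
#'
#' @param path Path to \code{calls.tsv}.
#' @return A \code{perturbation_calls} object restricted to tumor samples.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  req <- c("sample", "pathway", "ips", "mu", "sigma", "label")
  if (!all(req %in% colnames(df))) {
    stop("calls table must have columns: ", paste(req, collapse = ", "))
  }
  pw <- unique(df$pathway); sm <- unique(df$sample)
  labels <- matrix(NA_character_, length(pw), length(sm),
                   dimnames = list(pw, sm))
  scores <- matrix(NA_real_, length(pw), length(sm), dimnames = list(pw, sm))
  labels[cbind(df$pathway, df$sample)] <- df$label
  scores[cbind(df$pathway, df$sample)] <- df$ips
  null <- unique(df[, c("pathway", "mu", "sigma")])
  null <- null[match(pw, null$pathway), , drop = FALSE]
  null$n_normal <- NA_integer_
  grp <- stats::setNames(rep("tumor", length(sm)), sm)
  structure(list(labels = labels, scores = scores, null = null,
                 k = NA_real_, rule = NA_character_, sample_group = grp),
            class = "perturbation_calls")
}
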