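#' Wilcoxon screen for pathways whose strong/weak groups differ in iPS
#'
#' For each scored pathway, the iPS values of perturbed-strong tumor samples
#' are compared to those of perturbed-weak tumor samples with a two-sided
#' Wilcoxon rank-sum test (exact distribution when both groups have at most
#' 25 samples and no ties; normal approximation with tie correction
#' otherwise), followed by Benjamini-Hochberg FDR across all tested pathways.
#' Because the two groups are themselves defined by thresholding the same
#' iPS, this stage is close to tautological and usually significant; it is
#' retained for pipeline fidelity and can be skipped upstream.
#'
#' @param calls A \code{perturbation_calls} object.
#' @param min_group Minimum tumor samples per arm for a pathway to be tested
#'   (default 10).
#' @return Data frame with columns \code{pathway}, \code{n_strong},
#'   \code{n_weak}, \code{wilcoxon_p}, \code{fdr_q}, \code{tested}.
#' @export
differential_pathways <- function(calls, min_group = 10L) {
  stopifnot(inherits(calls, "perturbation_calls"))
  tum <- calls$sample_group == "tumor"
  labels <- calls$labels[, tum, drop = FALSE]
  scores <- calls$scores[, tum, drop = FALSE]
  pw <- rownames(labels)

  res <- data.frame(pathway = pw,
                    n_strong = rowSums(labels == "strong", na.rm = TRUE),
                    n_weak = rowSums(labels == "weak", na.rm = TRUE),
                    wilcoxon_p = NA_real_, fdr_q = NA_real_,
                    tested = FALSE, row.names = NULL, stringsAsFactors = FALSE)

  for (i in seq_along(pw)) {
    s <- scores[i, labels[i, ] == "strong" & !is.na(labels[i, ])]
    w <- scores[i, labels[i, ] == "weak" & !is.na(labels[i, ])]
    if (length(s) < min_group || length(w) < min_group) next
    exact <- length(s) <= 25L && length(w) <= 25L &&
      !anyDuplicated(c(s, w))
    res$wilcoxon_p[i] <- suppressWarnings(
      stats::wilcox.test(s, w, alternative = "two.sided",
                         exact = exact, correct = !exact)$p.value)
    res$tested[i] <- TRUE
  }
  n_skip <- sum(!res$tested)
  if (n_skip) {
    message(n_skip, " pathway(s) excluded from the Wilcoxon stage ",
            "(fewer than ", min_group, " samples in an arm)")
  }
  res$fdr_q[res$tested] <- stats::p.adjust(res$wilcoxon_p[res$tested],
                                           method = "BH")
  res
}

# Restricted mean survival time: area under the Kaplan-Meier curve of one
# group up to the horizon tau.
.rmst <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  t <- c(0, fit$time[fit$time <= tau], tau)
  s <- c(1, fit$surv[fit$time <= tau])
  sum(diff(t) * s)
}

#' Kaplan-Meier / log-rank screen of differential pathways
#'
#' Pathways passing the FDR stage are tested for a survival split between
#' their perturbed-strong and perturbed-weak tumor groups with the two-group
#' log-rank test. A pathway is prognosis-related when the log-rank p-value is
#' below \code{logrank_threshold} and the strong group has worse prognosis,
#' operationalized as a lower restricted mean survival time up to the largest
#' observed time across both arms.
#'
#' @param calls A \code{perturbation_calls} object.
#' @param clinical Data frame from [read_clinical()].
#' @param differential Data frame from [differential_pathways()], or
#'   \code{NULL} to screen every scored pathway (Wilcoxon stage skipped).
#' @param fdr_threshold FDR cutoff for entering the survival stage
#'   (default 0.05).
#' @param logrank_threshold Log-rank significance cutoff (default 0.005,
#'   strict).
#' @param min_group Minimum samples with clinical data per arm (default 10).
#' @return Data frame of class \code{prognosis_result} with per-pathway
#'   columns \code{n_strong}, \code{n_weak}, \code{wilcoxon_p}, \code{fdr_q},
#'   \code{logrank_p}, \code{direction} (\code{strong_worse},
#'   \code{strong_better} or \code{indeterminate}) and
#'   \code{is_prognosis_related}.
#' @export
survival_screen <- function(calls, clinical, differential = NULL,
                            fdr_threshold = 0.05, logrank_threshold = 0.005,
                            min_group = 10L) {
  stopifnot(inherits(calls, "perturbation_calls"))
  tum <- names(calls$sample_group)[calls$sample_group == "tumor"]
  clin <- clinical[clinical$sample_id %in% tum, , drop = FALSE]

  pw <- rownames(calls$labels)
  res <- data.frame(pathway = pw, n_strong = NA_integer_,
                    n_weak = NA_integer_,
                    wilcoxon_p = NA_real_, fdr_q = NA_real_,
                    logrank_p = NA_real_, direction = "indeterminate",
                    is_prognosis_related = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(differential)) {
    idx <- match(pw, differential$pathway)
    res$wilcoxon_p <- differential$wilcoxon_p[idx]
    res$fdr_q <- differential$fdr_q[idx]
    screen <- !is.na(res$fdr_q) & res$fdr_q < fdr_threshold
  } else {
    screen <- rowSums(!is.na(calls$labels[, tum, drop = FALSE])) > 0L
  }

  for (i in which(screen)) {
    lab <- calls$labels[i, tum]
    lab <- lab[!is.na(lab)]
    dat <- clin[clin$sample_id %in% names(lab), , drop = FALSE]
    dat$group <- lab[dat$sample_id]
    ns <- sum(dat$group == "strong"); nw <- sum(dat$group == "weak")
    res$n_strong[i] <- ns; res$n_weak[i] <- nw
    if (ns < min_group || nw < min_group) {
      message("pathway ", pw[i], " excluded from survival stage (",
              ns, " strong / ", nw, " weak with clinical data)")
      next
    }
    sd_fit <- survival::survdiff(
      survival::Surv(time, event) ~ group, data = dat)
    p <- stats::pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE)
    res$logrank_p[i] <- p
    tau <- max(dat$time)
    rm_s <- .rmst(dat$time[dat$group == "strong"],
                  dat$event[dat$group == "strong"], tau)
    rm_w <- .rmst(dat$time[dat$group == "weak"],
                  dat$event[dat$group == "weak"], tau)
    res$direction[i] <- if (rm_s < rm_w) "strong_worse"
      else if (rm_s > rm_w) "strong_better" else "indeterminate"
    res$is_prognosis_related[i] <- p < logrank_threshold &&
      res$direction[i] == "strong_worse"
  }
  attr(res, "thresholds") <- list(fdr = fdr_threshold,
                                  logrank = logrank_threshold,
                                  min_group = as.integer(min_group))
  class(res) <- c("prognosis_result", class(res))
  res
}

#' Kaplan-Meier step functions for one pathway's strong/weak groups
#'
#' Product-limit survival estimates per perturbation group, in long format
#' suitable for TSV export and plotting; each group starts at (0, 1).
#'
#' @param calls A \code{perturbation_calls} object.
#' @param pathway Pathway name.
#' @param clinical Data frame from [read_clinical()].
#' @return Data frame with columns \code{group}, \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}.
#' @export
km_curve <- function(calls, pathway, clinical) {
  stopifnot(inherits(calls, "perturbation_calls"))
  if (!pathway %in% rownames(calls$labels)) {
    stop("unknown pathway: ", pathway)
  }
  tum <- names(calls$sample_group)[calls$sample_group == "tumor"]
  lab <- calls$labels[pathway, tum]
  lab <- lab[!is.na(lab)]
  dat <- clinical[clinical$sample_id %in% names(lab), , drop = FALSE]
  dat$group <- lab[dat$sample_id]
  out <- do.call(rbind, lapply(c("strong", "weak"), function(g) {
    d <- dat[dat$group == g, , drop = FALSE]
    if (!nrow(d)) stop("empty ", g, " group for pathway ", pathway)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    data.frame(group = g,
               time = c(0, fit$time), surv = c(1, fit$surv),
               n_risk = c(fit$n, fit$n.risk), n_event = c(0L, fit$n.event),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Gene connectivity within pathways
#'
#' Counts, for each gene of each named pathway, the number of retained edges
#' incident to it. High-degree genes are the pathway's hubs; in prognostic
#' pathways they are candidate driver genes.
#'
#' @param edges A \code{pathway_edges} object.
#' @param pathway_names Pathways to tabulate (default: all).
#' @return Data frame with columns \code{pathway}, \code{gene}, \code{degree},
#'   sorted by descending degree within pathway.
#' @export
gene_degree <- function(edges, pathway_names = names(edges)) {
  stopifnot(inherits(edges, "pathway_edges"))
  unknown <- setdiff(pathway_names, names(edges))
  if (length(unknown)) {
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  }
  out <- do.call(rbind, lapply(pathway_names, function(p) {
    tab <- table(c(edges[[p]][, "gene_a"], edges[[p]][, "gene_b"]))
    df <- data.frame(pathway = p, gene = names(tab),
                     degree = as.integer(tab), stringsAsFactors = FALSE)
    df[order(-df$degree, df$gene), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}
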