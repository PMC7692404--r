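# exact two-sided rank-sum p by exhaustive enumeration over group assignments
enumerate_wilcoxon_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  r <- rank(pooled)
  n1 <- length(g1)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(combn(length(pooled), n1), 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(all_w <= w_obs); p_ge <- mean(all_w >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# log-rank chi-square from the standard observed-minus-expected sums
logrank_p_oracle <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at1 <- sum(time >= t & group == 1); at2 <- sum(time >= t & group == 2)
    d1 <- sum(time == t & event == 1 & group == 1)
    d2 <- sum(time == t & event == 1 & group == 2)
    d <- d1 + d2; n <- at1 + at2
    if (n < 2) next
    o1 <- o1 + d1
    e1 <- e1 + d * at1 / n
    v <- v + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  stats::pchisq((o1 - e1)^2 / v, df = 1, lower.tail = FALSE)
}

make_calls <- function(labels_row, scores_row, pathway = "P1") {
  sm <- names(labels_row)
  labels <- matrix(labels_row, 1, dimnames = list(pathway, sm))
  scores <- matrix(scores_row, 1, dimnames = list(pathway, sm))
  structure(list(labels = labels, scores = scores,
                 null = data.frame(pathway = pathway, mu = NA_real_,
                                   sigma = NA_real_, n_normal = NA_integer_),
                 k = 2, rule = "two_sided",
                 sample_group = stats::setNames(rep("tumor", length(sm)), sm)),
            class = "perturbation_calls")
}

test_that("the Wilcoxon stage reproduces the exact enumeration p-value", {
  sm <- paste0("T", 1:6)
  calls <- make_calls(stats::setNames(c(rep("weak", 3), rep("strong", 3)), sm),
                      stats::setNames(c(1, 2, 3, 4, 5, 6), sm))
  res <- differential_pathways(calls, min_group = 3)
  expect_equal(res$wilcoxon_p, 0.1, tolerance = 1e-9)
  expect_equal(res$wilcoxon_p, enumerate_wilcoxon_p(c(4, 5, 6), c(1, 2, 3)),
               tolerance = 1e-12)
  expect_identical(res$n_strong, 3); expect_identical(res$n_weak, 3)

  # identical score distributions: p = 1
  calls2 <- make_calls(stats::setNames(c(rep("weak", 3), rep("strong", 3)), sm),
                       stats::setNames(rep(c(1, 2, 3), 2), sm))
  expect_equal(differential_pathways(calls2, min_group = 3)$wilcoxon_p, 1,
               tolerance = 1e-9)

  # an arm below min_group excludes the pathway from testing
  expect_message(
    res3 <- differential_pathways(calls, min_group = 4), "excluded")
  expect_false(res3$tested)
})

test_that("BH adjustment is the step-up transform and permutation-stable", {
  p <- c(0.01, 0.02, 0.04, 0.05)
  # independent step-up oracle
  bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    q <- rev(cummin(rev(p[order(p)] * n / seq_len(n))))
    q[rank(p, ties.method = "first")]
  }
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.05, 0.05),
               tolerance = 1e-12)
  expect_equal(bh(p), c(0.04, 0.04, 0.05, 0.05), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  expect_equal(stats::p.adjust(p[perm], "BH"), stats::p.adjust(p, "BH")[perm],
               tolerance = 1e-12)
})

test_that("survival screen matches an independent log-rank computation", {
  sm <- paste0("T", 1:6)
  calls <- make_calls(stats::setNames(c(rep("strong", 3), rep("weak", 3)), sm),
                      stats::setNames(c(5, 6, 7, 1, 2, 3), sm))
  clinical <- data.frame(sample_id = sm,
                         time = c(10, 20, 30, 100, 200, 300),
                         event = rep(1L, 6), stringsAsFactors = FALSE)
  res <- survival_screen(calls, clinical, differential = NULL, min_group = 3)
  expect_identical(res$direction, "strong_worse")
  p_ref <- logrank_p_oracle(clinical$time, clinical$event,
                            c(1, 1, 1, 2, 2, 2))
  expect_equal(res$logrank_p, p_ref, tolerance = 1e-6)

  # identical arms: p = 1, no direction
  clin_same <- data.frame(sample_id = sm, time = rep(c(10, 20, 30), 2),
                          event = rep(1L, 6), stringsAsFactors = FALSE)
  res2 <- survival_screen(calls, clin_same, differential = NULL, min_group = 3)
  expect_equal(res2$logrank_p, 1, tolerance = 1e-9)
  expect_identical(res2$direction, "indeterminate")
  expect_false(res2$is_prognosis_related)
})

test_that("a pathway with better strong-arm survival is never flagged", {
  sm <- paste0("T", 1:40)
  lab <- stats::setNames(c(rep("strong", 20), rep("weak", 20)), sm)
  calls <- make_calls(lab, stats::setNames(c(rep(2, 20), rep(1, 20)), sm))
  set.seed(5)
  clinical <- data.frame(sample_id = sm,
                         time = c(rexp(20, 1 / 300), rexp(20, 1 / 30)),
                         event = 1L, stringsAsFactors = FALSE)
  res <- survival_screen(calls, clinical, differential = NULL, min_group = 10)
  expect_identical(res$direction, "strong_better")
  expect_false(res$is_prognosis_related)
})

test_that("a planted hazard-ratio split is detected as prognosis-related", {
  set.seed(21)
  sm <- paste0("T", 1:200)
  lab <- stats::setNames(c(rep("strong", 100), rep("weak", 100)), sm)
  calls <- make_calls(lab, stats::setNames(c(rnorm(100, 3), rnorm(100, 1)), sm))
  rate <- ifelse(lab == "strong", 3 / 365, 1 / 365)
  t_ev <- rexp(200, rate)
  cens <- runif(200) < 0.2
  clinical <- data.frame(sample_id = sm,
                         time = ifelse(cens, runif(200) * t_ev, t_ev),
                         event = as.integer(!cens), stringsAsFactors = FALSE)
  d <- differential_pathways(calls)
  res <- survival_screen(calls, clinical, differential = d)
  expect_true(res$is_prognosis_related)
  expect_identical(res$direction, "strong_worse")
  expect_lt(res$logrank_p, 0.005)
})

test_that("Kaplan-Meier curves reproduce the hand product-limit estimate", {
  sm <- paste0("T", 1:6)
  lab <- stats::setNames(c(rep("strong", 3), rep("weak", 3)), sm)
  calls <- make_calls(lab, stats::setNames(rep(1, 6), sm))
  clinical <- data.frame(sample_id = sm,
                         time = c(1, 2, 3, 5, 6, 7),
                         event = c(1L, 1L, 0L, 1L, 1L, 1L),
                         stringsAsFactors = FALSE)
  km <- km_curve(calls, "P1", clinical)
  s <- km[km$group == "strong", ]
  expect_equal(s$time, c(0, 1, 2, 3))
  expect_equal(s$surv, c(1, 2 / 3, 1 / 3, 1 / 3), tolerance = 1e-9)
  # no events: survival stays 1
  clin_ne <- transform(clinical, event = 0L)
  km2 <- km_curve(calls, "P1", clin_ne)
  expect_true(all(km2$surv == 1))
  expect_error(km_curve(calls, "nope", clinical), "unknown pathway")
})

test_that("gene degrees follow the handshake lemma", {
  edges <- make_edges(list(
    TRI = rbind(c("A", "B"), c("A", "C"), c("B", "C")),
    STAR = rbind(c("A", "B"), c("A", "C"), c("A", "D"))))
  deg <- gene_degree(edges)
  tri <- deg[deg$pathway == "TRI", ]
  expect_true(all(tri$degree == 2))
  star <- deg[deg$pathway == "STAR", ]
  expect_identical(star$degree[star$gene == "A"], 3L)
  expect_true(all(star$degree[star$gene != "A"] == 1L))

  set.seed(8)
  for (i in 1:5) {
    g <- paste0("G", 1:8)
    pairs <- t(combn(g, 2))
    pairs <- pairs[sample(nrow(pairs), 12), ]
    e <- make_edges(list(P = pairs))
    d <- gene_degree(e)
    expect_identical(sum(d$degree), 2L * 12L)
  }
  expect_error(gene_degree(edges, "missing_pw"), "unknown pathway")
})
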