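#' Configuration for a synthetic cohort with planted perturbations
#'
#' The generator emulates the statistical structure the scoring pipeline
#' assumes: normal samples whose pathway gene blocks are equicorrelated at
#' \code{rho} on a latent Gaussian scale, tumor samples of which a fraction
#' carry a planted correlation perturbation on designated pathways
#' (\code{decorrelate}: within-block correlation removed; \code{sign_flip}:
#' half of the block's loadings negated so cross-pair correlations flip to
#' \code{-rho}), and exponential survival whose hazard is multiplied by
#' \code{hazard_ratio_strong} for carriers on a survival pathway. Expression
#' is made nonnegative by exponentiating the latent field (log-normal, as in
#' right-skewed normalized RNA-seq); correlations are therefore realized on
#' the emitted scale and reported in the truth table.
#'
#' @param seed Integer RNG seed; the single source of randomness.
#' @param n_normal,n_tumor Sample counts.
#' @param n_pathways,genes_per_pathway Disjoint gene blocks, one per pathway.
#' @param rho Latent within-block correlation in (-1, 1).
#' @param perturbed_pathways Names (or indices) of pathways carrying a
#'   planted perturbation in tumors.
#' @param perturbation_mode \code{"decorrelate"} or \code{"sign_flip"}.
#' @param fraction_tumors_perturbed Fraction of tumor samples that carry the
#'   perturbation, drawn independently per perturbed pathway.
#' @param survival_pathways Perturbed pathways whose carriers get the raised
#'   hazard.
#' @param hazard_ratio_strong Multiplicative hazard for carriers (> 0).
#' @param baseline_hazard Baseline exponential hazard per day.
#' @param censoring_fraction Expected fraction of censored tumor samples,
#'   in [0, 1).
#' @param sigma_log Latent log-scale standard deviation; small values keep
#'   the realized (log-normal) correlation close to \code{rho}.
#' @param edges_per_pathway Cap on edges per pathway (default: all
#'   within-block pairs).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_normal = 100L, n_tumor = 200L,
                       n_pathways = 10L, genes_per_pathway = 40L,
                       rho = 0.8,
                       perturbed_pathways = c("PW01", "PW02"),
                       perturbation_mode = c("decorrelate", "sign_flip"),
                       fraction_tumors_perturbed = 0.5,
                       survival_pathways = "PW01",
                       hazard_ratio_strong = 3,
                       baseline_hazard = 1 / 365,
                       censoring_fraction = 0.2,
                       sigma_log = 0.15,
                       edges_per_pathway = Inf) {
  perturbation_mode <- match.arg(perturbation_mode)
  stopifnot(n_normal >= 3L, n_tumor >= 1L, n_pathways >= 1L,
            genes_per_pathway >= 2L,
            rho > -1, rho < 1,
            fraction_tumors_perturbed >= 0, fraction_tumors_perturbed <= 1,
            hazard_ratio_strong > 0, baseline_hazard > 0,
            censoring_fraction >= 0, censoring_fraction < 1,
            sigma_log > 0)
  pw_names <- sprintf("PW%02d", seq_len(n_pathways))
  if (is.numeric(perturbed_pathways)) {
    perturbed_pathways <- pw_names[perturbed_pathways]
  }
  if (is.numeric(survival_pathways)) {
    survival_pathways <- pw_names[survival_pathways]
  }
  if (!all(perturbed_pathways %in% pw_names)) {
    stop("perturbed_pathways outside the simulated pathway set")
  }
  if (!all(survival_pathways %in% perturbed_pathways)) {
    stop("survival_pathways must be a subset of perturbed_pathways")
  }
  structure(list(seed = as.integer(seed), n_normal = as.integer(n_normal),
                 n_tumor = as.integer(n_tumor),
                 n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 rho = rho, pathway_names = pw_names,
                 perturbed_pathways = perturbed_pathways,
                 perturbation_mode = perturbation_mode,
                 fraction_tumors_perturbed = fraction_tumors_perturbed,
                 survival_pathways = survival_pathways,
                 hazard_ratio_strong = hazard_ratio_strong,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 sigma_log = sigma_log,
                 edges_per_pathway = edges_per_pathway),
            class = "sim_config")
}

# Equicorrelated latent block: z = sqrt(rho) * f + sqrt(1 - rho) * e with a
# shared factor f per sample. Negative rho uses a negated loading on half the
# genes (the same construction as sign_flip), since a common factor cannot
# produce uniformly negative equicorrelation for blocks larger than two.
.latent_block <- function(n_samples, n_genes, rho, flip_half = FALSE) {
  f <- stats::rnorm(n_samples)
  e <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  if (rho == 0) return(e)
  load <- rep(sqrt(abs(rho)), n_genes)
  if (flip_half || rho < 0) {
    load[seq_len(n_genes) %% 2L == 0L] <- -load[seq_len(n_genes) %% 2L == 0L]
  }
  outer(f, load) + sqrt(1 - abs(rho)) * e
}

#' Simulate a full synthetic cohort
#'
#' Generates expression, pathway edge list, tumor clinical outcomes and a
#' ground-truth table under the given configuration. Identical configurations
#' (including seed) yield identical outputs; the global RNG state is restored
#' on exit.
#'
#' @param config A [sim_config()].
#' @return List with \code{expression} (an \code{expr_matrix}),
#'   \code{edges} (a \code{pathway_edges}), \code{clinical} (tumor samples),
#'   \code{truth} (list: \code{samples} data frame of per-pathway carrier
#'   status, \code{pathways} data frame with planted flags and realized
#'   normal within-block correlation) and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  gpp <- config$genes_per_pathway
  n_genes <- config$n_pathways * gpp
  genes <- sprintf("G%04d", seq_len(n_genes))
  block_of <- rep(config$pathway_names, each = gpp)
  n_n <- config$n_normal; n_t <- config$n_tumor
  normals <- sprintf("N%03d", seq_len(n_n))
  tumors <- sprintf("T%03d", seq_len(n_t))

  # carriers drawn independently per perturbed pathway so that planted
  # survival effects are attributable to their own pathway only
  n_carry <- round(config$fraction_tumors_perturbed * n_t)
  carriers <- lapply(config$perturbed_pathways, function(p) {
    sort(sample.int(n_t, n_carry))
  })
  names(carriers) <- config$perturbed_pathways

  z <- matrix(0, n_n + n_t, n_genes)
  for (b in seq_len(config$n_pathways)) {
    p <- config$pathway_names[b]
    cols <- which(block_of == p)
    z[seq_len(n_n), cols] <- .latent_block(n_n, gpp, config$rho)
    tum_rows <- n_n + seq_len(n_t)
    if (p %in% config$perturbed_pathways) {
      carry <- carriers[[p]]
      noncarry <- setdiff(seq_len(n_t), carry)
      if (length(noncarry)) {
        z[n_n + noncarry, cols] <- .latent_block(length(noncarry), gpp,
                                                 config$rho)
      }
      if (length(carry)) {
        z[n_n + carry, cols] <- switch(
          config$perturbation_mode,
          decorrelate = .latent_block(length(carry), gpp, 0),
          sign_flip = .latent_block(length(carry), gpp, config$rho,
                                    flip_half = TRUE))
      }
    } else {
      z[tum_rows, cols] <- .latent_block(n_t, gpp, config$rho)
    }
  }
  mu_g <- stats::runif(n_genes, log(5), log(50))
  values <- exp(sweep(config$sigma_log * t(z), 1L, mu_g, `+`))
  dimnames(values) <- list(genes, c(normals, tumors))

  grp <- stats::setNames(c(rep("normal", n_n), rep("tumor", n_t)),
                         c(normals, tumors))
  expression <- structure(list(values = values, sample_group = grp,
                               subtype = NULL, cohort_label = "synthetic",
                               log_transformed = FALSE),
                          class = "expr_matrix")

  edges <- lapply(config$pathway_names, function(p) {
    g <- genes[block_of == p]
    pairs <- t(utils::combn(g, 2L))
    if (is.finite(config$edges_per_pathway) &&
        nrow(pairs) > config$edges_per_pathway) {
      pairs <- pairs[seq_len(config$edges_per_pathway), , drop = FALSE]
    }
    cbind(gene_a = pmin(pairs[, 1L], pairs[, 2L]),
          gene_b = pmax(pairs[, 1L], pairs[, 2L]))
  })
  names(edges) <- config$pathway_names
  class(edges) <- "pathway_edges"
  attr(edges, "dropped") <- data.frame(pathway = config$pathway_names,
                                       n_dropped = 0L,
                                       stringsAsFactors = FALSE)

  # survival: exponential with raised hazard for carriers on survival pathways
  at_risk <- rep(FALSE, n_t)
  for (p in config$survival_pathways) at_risk[carriers[[p]]] <- TRUE
  rate <- config$baseline_hazard *
    ifelse(at_risk, config$hazard_ratio_strong, 1)
  t_event <- stats::rexp(n_t, rate = rate)
  censored <- stats::runif(n_t) < config$censoring_fraction
  obs_time <- ifelse(censored, stats::runif(n_t) * t_event, t_event)
  clinical <- data.frame(sample_id = tumors, time = obs_time,
                         event = as.integer(!censored),
                         stringsAsFactors = FALSE)

  truth_samples <- do.call(rbind, lapply(config$pathway_names, function(p) {
    data.frame(sample_id = tumors, pathway = p,
               is_perturbed = if (p %in% config$perturbed_pathways)
                 seq_len(n_t) %in% carriers[[p]] else FALSE,
               stringsAsFactors = FALSE)
  }))
  realized_rho <- vapply(config$pathway_names, function(p) {
    v <- t(values[block_of == p, normals, drop = FALSE])
    cm <- stats::cor(v)
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  truth_pathways <- data.frame(
    pathway = config$pathway_names,
    is_perturbed = config$pathway_names %in% config$perturbed_pathways,
    is_survival_pathway = config$pathway_names %in% config$survival_pathways,
    realized_normal_rho = realized_rho,
    stringsAsFactors = FALSE)

  list(expression = expression, edges = edges, clinical = clinical,
       truth = list(samples = truth_samples, pathways = truth_pathways),
       config = config)
}

#' Write a simulated cohort to the package's external TSV formats
#'
#' @param cohort A list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisible named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(expression = file.path(dir, "expression.tsv"),
         annotation = file.path(dir, "annotation.tsv"),
         pathways = file.path(dir, "pathways.tsv"),
         clinical = file.path(dir, "clinical.tsv"),
         truth_samples = file.path(dir, "truth_samples.tsv"),
         truth_pathways = file.path(dir, "truth_pathways.tsv"))
  write_expression(cohort$expression, f[["expression"]], f[["annotation"]])
  pw_rows <- do.call(rbind, lapply(names(cohort$edges), function(p) {
    cbind(p, cohort$edges[[p]])
  }))
  utils::write.table(pw_rows, f[["pathways"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  clin <- cohort$clinical
  colnames(clin)[colnames(clin) == "time"] <- "time_days"
  utils::write.table(clin, f[["clinical"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth$samples, f[["truth_samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$pathways, f[["truth_pathways"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(f)
}

#' Write the canonical small fixture suite
#'
#' Emits, in the package's external formats, the small data sets used across
#' the documentation and tests: the hand-checked three-normal edge fixture,
#' a three-pathway toy cohort, and the standard planted-prognosis cohort.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the generated cohorts.
#' @return Invisible list of per-fixture file vectors.
#' @export
write_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # hand-checked edge fixture: three normals, values chosen so that
  # cor(x, y) = 0.5 for (1,2,3) vs (1,3,2) and 1.0 for (1,2,3) vs (2,4,6)
  hand_dir <- file.path(out_dir, "hand_edges")
  dir.create(hand_dir, showWarnings = FALSE)
  vals <- rbind(GX = c(1, 2, 3), GY = c(1, 3, 2), GZ = c(2, 4, 6))
  colnames(vals) <- c("N001", "N002", "N003")
  hand <- structure(list(values = vals,
                         sample_group = stats::setNames(rep("normal", 3L),
                                                        colnames(vals)),
                         subtype = NULL, cohort_label = "hand",
                         log_transformed = FALSE),
                    class = "expr_matrix")
  write_expression(hand, file.path(hand_dir, "expression.tsv"),
                   file.path(hand_dir, "annotation.tsv"))
  writeLines(c("PH\tGX\tGY", "PH\tGX\tGZ"),
             file.path(hand_dir, "pathways.tsv"))

  toy <- simulate_cohort(sim_config(seed = seed, n_normal = 12L,
                                    n_tumor = 12L, n_pathways = 3L,
                                    genes_per_pathway = 5L,
                                    perturbed_pathways = "PW01",
                                    survival_pathways = "PW01"))
  toy_f <- write_cohort(toy, file.path(out_dir, "toy_cohort"))

  planted <- simulate_cohort(sim_config(seed = seed))
  planted_f <- write_cohort(planted, file.path(out_dir, "planted_cohort"))

  invisible(list(hand = hand_dir, toy = toy_f, planted = planted_f))
}
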