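#' Configuration for a power / Type I error simulation study
#'
#' Bundles everything one Monte Carlo study needs: the scenario (`"power"`
#' draws cases and controls from different network designs, `"type1"` draws
#' every subject from the control design and assigns group labels at
#' random), the outcome family, the community detection algorithm, the
#' cluster evaluation metric, and the replication budget.
#'
#' @param scenario `"power"` or `"type1"`.
#' @param family `"binomial"` (outcome = group label, intercept-only null)
#'   or `"gaussian"` (simulated continuous outcome with two covariates in
#'   the null design).
#' @param algorithm `"louvain"` or `"spinglass"`.
#' @param metric `"purity"`, `"nmi"`, `"ari"`, or `"objective"`.
#' @param n_reps Monte Carlo replications.
#' @param n_networks subjects per replication.
#' @param case_fraction proportion of cases, in (0, 1).
#' @param case_design,control_design [sim_design()]s (must agree on
#'   `n_nodes`/`n_communities`).
#' @param alpha significance level.
#' @param shared_master if `TRUE` one master community assignment is drawn
#'   per replication and perturbed for every subject; if `FALSE` each group
#'   draws its own master (two distinct generating populations). The
#'   default (`NULL`) resolves to `FALSE` for the `"power"` scenario --
#'   under the alternative the groups are two separate generation
#'   processes -- and `TRUE` under `"type1"`, where all subjects come from
#'   one population.
#' @param outcome_model parameters of the gaussian outcome model: `beta0`,
#'   `beta1`, `eps_sd` for the power scenario, `null_mean`, `null_sd` for
#'   the type1 scenario, `cov_cont = c(mean, sd)` and `cov_bin_p` for the
#'   two covariates.
#' @param grid_points bandwidth grid size for [davies_test()].
#' @param sg_control spinglass settings passed to [detect_spinglass()]
#'   (`max_communities`, `gamma`, `t0`, `t_min`, `cool`, `sweeps`).
#' @param seed study-level seed; per-rep seeds are derived from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(scenario = c("power", "type1"),
                         family = c("binomial", "gaussian"),
                         algorithm = c("louvain", "spinglass"),
                         metric = c("nmi", "ari", "purity", "objective"),
                         n_reps = 300,
                         n_networks = 100,
                         case_fraction = 0.45,
                         case_design,
                         control_design,
                         alpha = 0.05,
                         shared_master = NULL,
                         outcome_model = list(),
                         grid_points = 50,
                         sg_control = list(),
                         seed = 1) {
  scenario <- match.arg(scenario)
  family <- match.arg(family)
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must lie strictly in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_reps < 1) stop("n_reps must be at least 1")
  om <- utils::modifyList(
    list(beta0 = 5, beta1 = -4, eps_sd = 2,
         cov_cont = c(10, 5), cov_bin_p = 0.25,
         null_mean = 100, null_sd = 15),
    outcome_model)
  sg <- utils::modifyList(
    list(max_communities = 4, gamma = 1, t0 = 1, t_min = 1e-3,
         cool = 0.99, sweeps = NULL),
    sg_control)
  if (is.null(shared_master)) shared_master <- scenario == "type1"
  structure(list(scenario = scenario, family = family, algorithm = algorithm,
                 metric = metric, n_reps = as.integer(n_reps),
                 n_networks = as.integer(n_networks),
                 case_fraction = case_fraction,
                 case_design = case_design, control_design = control_design,
                 alpha = alpha, shared_master = shared_master,
                 outcome_model = om,
                 grid_points = grid_points, sg_control = sg,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Named study presets
#'
#' The four simulation scenarios of the power/Type-I study: 100 networks of
#' 50 nodes and three planted communities per replication, 45/55
#' case/control split, perturbation probability 0.1, between-community
#' weights `Beta(1.5, 8)` everywhere, within-community weights `Beta(7, 8)`
#' for cases and `Beta(8, 8)` for controls (power scenarios; the type1
#' scenarios draw every subject from the control design). The gaussian
#' scenarios add a `N(10, 5)` continuous and a `Bernoulli(0.25)` binary
#' covariate, with outcome `y = 5 - 4*case + N(0, 2)` under the alternative
#' and `y ~ N(100, 15)` under the null.
#'
#' @param name one of `"logistic-power"`, `"logistic-type1"`,
#'   `"linear-power"`, `"linear-type1"`.
#' @param ... overrides passed on to [study_config()] (e.g. `n_reps`,
#'   `metric`, `algorithm`, `seed`).
#' @return A `study_config`.
#' @export
#' @examples
#' preset_config("logistic-power", n_reps = 10, seed = 3)
preset_config <- function(name = c("logistic-power", "logistic-type1",
                                   "linear-power", "linear-type1"),
                          ...) {
  name <- match.arg(name)
  case_d <- sim_design(50, 3, within = c(7, 8), between = c(1.5, 8),
                       perturb_prob = 0.1)
  ctrl_d <- sim_design(50, 3, within = c(8, 8), between = c(1.5, 8),
                       perturb_prob = 0.1)
  family <- if (startsWith(name, "logistic")) "binomial" else "gaussian"
  scenario <- if (endsWith(name, "power")) "power" else "type1"
  study_config(scenario = scenario, family = family,
               case_design = case_d, control_design = ctrl_d,
               n_networks = 100, case_fraction = 0.45, ...)
}

# One replication shared across several family x metric cells: simulate the
# cohort once, detect once, reuse the partitions for every requested
# distance metric and outcome family. Returns a families x metrics matrix
# of Davies p-values.
rep_pvalues <- function(config, rep_seed,
                        metrics = config$metric, families = config$family) {
  set.seed(rep_seed)
  n_case <- round(config$case_fraction * config$n_networks)
  n_control <- config$n_networks - n_case
  if (config$scenario == "power") {
    coh <- simulate_cohort(n_case, n_control,
                           config$case_design, config$control_design,
                           shared_master = config$shared_master)
    group <- coh$group
  } else {
    coh <- simulate_cohort(0, config$n_networks,
                           config$control_design, config$control_design,
                           shared_master = TRUE)
    group <- sample(rep(c(1L, 0L), c(n_case, n_control)))
  }
  parts <- if (config$algorithm == "louvain") {
    lapply(coh$networks, detect_louvain)
  } else {
    sg <- config$sg_control
    lapply(coh$networks, detect_spinglass,
           max_communities = sg$max_communities, gamma = sg$gamma,
           t0 = sg$t0, t_min = sg$t_min, cool = sg$cool, sweeps = sg$sweeps)
  }
  dists <- list()
  extr <- intersect(metrics, c("purity", "nmi", "ari"))
  if (length(extr)) {
    dd <- pairwise_extrinsic_dists(parts)
    for (m in extr) {
      x <- dd[[m]]
      x[x < 0] <- 0
      dists[[m]] <- subject_dist(x, coh$subject_ids, metric = m)
    }
  }
  if ("objective" %in% metrics)
    dists$objective <- partition_distances(parts, "objective",
                                           subject_ids = coh$subject_ids)

  om <- config$outcome_model
  n <- config$n_networks
  outcomes <- list()
  if ("binomial" %in% families)
    outcomes$binomial <- list(y = group, X = NULL)
  if ("gaussian" %in% families) {
    x1 <- rnorm(n, om$cov_cont[1], om$cov_cont[2])
    x2 <- rbinom(n, 1, om$cov_bin_p)
    y <- if (config$scenario == "power")
      om$beta0 + om$beta1 * (group == 1L) + rnorm(n, 0, om$eps_sd)
    else rnorm(n, om$null_mean, om$null_sd)
    outcomes$gaussian <- list(y = y, X = cbind(`(Intercept)` = 1, x1 = x1, x2 = x2))
  }

  p <- matrix(NA_real_, length(families), length(metrics),
              dimnames = list(families, metrics))
  for (fam in families)
    for (m in metrics)
      p[fam, m] <- davies_test(dists[[m]], outcomes[[fam]]$y,
                               outcomes[[fam]]$X, family = fam,
                               grid_points = config$grid_points,
                               check_kernel = FALSE)$p_value
  p
}

#' Run one study replication
#'
#' Simulate a cohort, detect communities, build the configured distance
#' matrix, generate the outcome, and run the Davies score test.
#'
#' @param config a [study_config()].
#' @param rep_seed integer seed for this replication; the returned p-value
#'   is a deterministic function of `(config, rep_seed)`.
#' @return The Davies-bound p-value.
#' @export
run_rep <- function(config, rep_seed) {
  stopifnot(inherits(config, "study_config"))
  rep_pvalues(config, rep_seed)[config$family, config$metric]
}

derive_rep_seeds <- function(seed, n_reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Run a Monte Carlo power / Type I error study
#'
#' Executes `config$n_reps` independent replications (seeds derived from
#' `config$seed`) and reports the empirical rejection rate at
#' `config$alpha` -- the power under the `"power"` scenario, the Type I
#' error under `"type1"` -- with its binomial Monte Carlo standard error
#' \eqn{\sqrt{\hat p(1-\hat p)/n_{reps}}}.
#'
#' @param config a [study_config()].
#' @return Object of class `study_summary`: `rejection_rate`, `mc_se`,
#'   `p_values`, `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_rep_seeds(config$seed, config$n_reps)
  pv <- vapply(seeds, function(s) run_rep(config, s), numeric(1))
  new_study_summary(pv, config, config$family, config$metric)
}

new_study_summary <- function(p_values, config, family, metric) {
  rate <- mean(p_values < config$alpha)
  structure(list(rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / length(p_values)),
                 p_values = p_values,
                 n_reps = length(p_values),
                 scenario = config$scenario, family = family,
                 algorithm = config$algorithm, metric = metric,
                 alpha = config$alpha, config = config),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> %s / %s / %s / %s: %s = %.3f (MC-SE %.3f, %d reps)\n",
              x$scenario, x$family, x$algorithm, x$metric,
              if (x$scenario == "power") "power" else "Type I error",
              x$rejection_rate, x$mc_se, x$n_reps))
  invisible(x)
}

#' Run one scenario for several metrics and families at once
#'
#' The expensive stages of a replication (cohort simulation, community
#' detection) do not depend on the metric or the outcome family, so a
#' whole row of the results table can share them. Runs `config$n_reps`
#' replications and returns one [run_study()]-style summary per
#' family x metric cell.
#'
#' @param config a [study_config()]; its `family`/`metric` fields are
#'   ignored in favor of the arguments.
#' @param metrics character vector of metrics to evaluate.
#' @param families character vector of outcome families.
#' @return Named list of `study_summary` objects (`"<family>.<metric>"`).
#' @export
run_study_multi <- function(config,
                            metrics = c("objective", "nmi", "ari", "purity"),
                            families = config$family) {
  stopifnot(inherits(config, "study_config"))
  seeds <- derive_rep_seeds(config$seed, config$n_reps)
  pv <- lapply(seeds, function(s) rep_pvalues(config, s, metrics, families))
  out <- list()
  for (fam in families)
    for (m in metrics) {
      p <- vapply(pv, function(x) x[fam, m], numeric(1))
      out[[paste(fam, m, sep = ".")]] <- new_study_summary(p, config, fam, m)
    }
  out
}

#' Arrange study summaries as a results table
#'
#' Lays out a collection of study summaries as the familiar
#' metric-by-(algorithm x scenario) grid, one row per metric, entries
#' formatted as `rate (SE: se)`.
#'
#' @param summaries list of `study_summary` objects sharing one alpha.
#' @param digits digits for the rate and SE.
#' @return A data.frame; metrics as rows, one column per
#'   algorithm/scenario combination present.
#' @export
summarize_tables <- function(summaries, digits = 3) {
  if (length(summaries) == 0) return(data.frame())
  alphas <- unique(vapply(summaries, `[[`, numeric(1), "alpha"))
  if (length(alphas) > 1) stop("summaries mix different alpha levels")
  long <- do.call(rbind, lapply(summaries, function(s)
    data.frame(metric = s$metric, algorithm = s$algorithm,
               scenario = s$scenario, family = s$family,
               rate = s$rejection_rate, mc_se = s$mc_se,
               stringsAsFactors = FALSE)))
  metrics <- unique(long$metric)
  cols <- unique(long[, c("family", "algorithm", "scenario")])
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cols))) {
    nm <- paste(cols$family[i], cols$algorithm[i], cols$scenario[i], sep = ".")
    sel <- long$family == cols$family[i] & long$algorithm == cols$algorithm[i] &
      long$scenario == cols$scenario[i]
    sub <- long[sel, ]
    out[[nm]] <- vapply(metrics, function(m) {
      j <- which(sub$metric == m)
      if (length(j) == 0) return(NA_character_)
      sprintf(paste0("%.", digits, "f (SE: %.", digits, "f)"),
              sub$rate[j[1]], sub$mc_se[j[1]])
    }, character(1))
  }
  attr(out, "alpha") <- alphas
  out
}
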