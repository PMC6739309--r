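# Binomial-GLM fitting and BIC-driven subset selection. Model fitting goes
# through stats::glm (binomial family); the search machinery — marginality
# constrained effect subsets, the exhaustive enumerator and the genetic
# algorithm — is implemented here. Effects are biomarker names for main
# effects and "A:B" for pairwise interactions; concentration covariates are
# log-transformed by default before entering the design.

effect_parents <- function(effect) strsplit(effect, ":", fixed = TRUE)[[1]]

is_interaction <- function(effect) grepl(":", effect, fixed = TRUE)

#' Default candidate effect space around a primary biomarker
#'
#' Main effects for the primary biomarker and each covariate, plus every
#' pairwise interaction involving the primary biomarker.
#'
#' @param primary primary biomarker name.
#' @param covariates covariate biomarker names.
#' @return Character vector of candidate effects.
#' @export
default_candidate_effects <- function(primary = "eNAPRT",
                                      covariates = c("CRP", "PCT", "WBC",
                                                     "Plts", "INR",
                                                     "eNAMPT")) {
  c(primary, covariates, paste(primary, covariates, sep = ":"))
}

# Marginality (hierarchy): an interaction may be included only when both of
# its main effects are included.
marginality_ok <- function(inclusion, candidates) {
  for (i in which(inclusion)) {
    p <- effect_parents(candidates[i])
    if (length(p) == 2 && !all(p %in% candidates[inclusion])) return(FALSE)
  }
  TRUE
}

# Drop orphan interactions until the inclusion vector is hierarchy-valid.
repair_marginality <- function(inclusion, candidates) {
  for (i in which(inclusion & vapply(candidates, is_interaction,
                                     logical(1)))) {
    p <- effect_parents(candidates[i])
    if (!all(p %in% candidates[inclusion])) inclusion[i] <- FALSE
  }
  inclusion
}

# Complete-case design matrix for a set of effects (list: X data.frame
# without intercept, y outcome vector, dropped row count).
build_design <- function(cohort, effects, outcome = "outcome",
                         log_transform = TRUE) {
  vars <- unique(unlist(lapply(effects, effect_parents)))
  cols <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown effect variable '", v, "'", call. = FALSE)
    x
  })
  names(cols) <- vars
  y <- cohort[[outcome]]
  cc <- stats::complete.cases(as.data.frame(c(cols, list(.y = y))))
  tr <- lapply(cols, function(x) {
    x <- x[cc]
    if (log_transform) log(pmax(x, .Machine$double.eps)) else x
  })
  X <- data.frame(row.names = seq_len(sum(cc)))
  for (ef in effects) {
    p <- effect_parents(ef)
    X[[ef]] <- if (length(p) == 1) tr[[p]] else tr[[p[1]]] * tr[[p[2]]]
  }
  list(X = X, y = y[cc], dropped = sum(!cc))
}

#' Fit a binomial (logistic) GLM
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial family, canonical logit link), converging when
#' the relative deviance change falls below 1e-8 or after 100 iterations.
#' BIC = -2 loglik + k ln n with k counting the intercept.
#'
#' @param design data.frame of predictors (no intercept column).
#' @param outcome binary response vector, same length as `nrow(design)`.
#' @return Object of class `glm_fit`: `coefficients`, `se`, `loglik`,
#'   `deviance`, `n`, `k`, `bic`, `converged`, `separation`, and the fitted
#'   probabilities `fitted`.
#' @export
fit_logistic_glm <- function(design, outcome) {
  stopifnot(is.data.frame(design), nrow(design) == length(outcome) ||
              ncol(design) == 0)
  n <- length(outcome)
  dat <- if (ncol(design)) design else data.frame(row.names = seq_len(n))
  dat$.y <- outcome
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  k <- length(cf)
  if (n <= k) stop("more parameters than observations", call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  separation <- any(abs(cf) > 15) &&
    (any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
  structure(list(coefficients = cf,
                 se = summary(fit)$coefficients[, "Std. Error"],
                 loglik = ll, deviance = fit$deviance, n = n, k = k,
                 bic = -2 * ll + k * log(n),
                 converged = fit$converged, separation = separation,
                 fitted = fit$fitted.values),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> n=%d, k=%d, deviance=%.4g, BIC=%.4g%s\n",
              x$n, x$k, x$deviance, x$bic,
              if (x$separation) " [separation]" else ""))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

# Fit an effect subset on a cohort; used by the oracle and the GA.
fit_effect_set <- function(cohort, effects, outcome = "outcome",
                           log_transform = TRUE) {
  d <- build_design(cohort, effects, outcome, log_transform)
  fit <- fit_logistic_glm(d$X, d$y)
  fit$effects <- effects
  fit
}

#' Analysis-of-deviance comparison of two nested binomial GLMs
#'
#' The deviance difference is referred to a chi-square with df equal to the
#' difference in parameter count.
#'
#' @param nested the smaller model (`glm_fit`).
#' @param full the larger model (`glm_fit`), fitted on the same data.
#' @return Two-sided p-value (1 for identical models).
#' @export
anova_deviance <- function(nested, full) {
  stopifnot(inherits(nested, "glm_fit"), inherits(full, "glm_fit"))
  if (nested$n != full$n)
    stop("models were fitted on different data", call. = FALSE)
  if (!all(nested$effects %in% c(full$effects)) && nested$k > 1)
    stop("models are not nested", call. = FALSE)
  df <- full$k - nested$k
  if (df < 0) stop("'full' has fewer parameters than 'nested'",
                   call. = FALSE)
  ddev <- nested$deviance - full$deviance
  if (ddev < -1e-6) stop("negative deviance difference: not nested fits",
                         call. = FALSE)
  if (df == 0) return(1)
  stats::pchisq(max(ddev, 0), df = df, lower.tail = FALSE)
}

# All hierarchy-valid inclusion vectors over <= 15 candidates.
enumerate_valid_subsets <- function(candidates) {
  L <- length(candidates)
  if (L == 0) return(matrix(logical(0), nrow = 1))
  if (L > 15) stop("exhaustive enumeration limited to 15 candidates",
                   call. = FALSE)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), L)))
  colnames(grid) <- candidates
  ok <- apply(grid, 1, marginality_ok, candidates = candidates)
  grid[ok, , drop = FALSE]
}

rank_models <- function(fits, inclusions) {
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  keys <- apply(inclusions, 1, function(v) paste(as.integer(v),
                                                 collapse = ""))
  ord <- order(bics, keys)
  list(fits = fits[ord], inclusions = inclusions[ord, , drop = FALSE],
       bic = bics[ord])
}

search_result <- function(ranked, candidates, method, trace = NULL,
                          seed = NULL, config = NULL) {
  structure(list(models = ranked$fits, inclusions = ranked$inclusions,
                 bic = ranked$bic, candidates = candidates,
                 method = method, trace = trace, seed = seed,
                 config = config),
            class = "model_search_result")
}

#' @export
print.model_search_result <- function(x, ...) {
  cat(sprintf("<model_search_result> %s search over %d candidate effect(s); %d model(s)\n",
              x$method, length(x$candidates), length(x$models)))
  top <- utils::head(seq_along(x$models), 5)
  for (i in top) {
    ef <- x$models[[i]]$effects
    cat(sprintf("  %d. BIC %.3f  {%s}\n", i, x$bic[i],
                if (length(ef)) paste(ef, collapse = ", ")
                else "intercept only"))
  }
  invisible(x)
}

#' Exhaustive BIC ranking over all hierarchy-valid effect subsets
#'
#' Fits every marginality-respecting subset of at most 15 candidate effects
#' and ranks the fits by ascending BIC (ties broken by the lexicographic
#' inclusion vector). Serves as ground truth for [ga_search()].
#'
#' @param cohort a [cohort_table()].
#' @param candidates candidate effects (mains and "A:B" interactions).
#' @param outcome outcome column name.
#' @param log_transform log-transform concentrations before fitting?
#' @return A `model_search_result` with `method = "exhaustive"`.
#' @export
exhaustive_oracle <- function(cohort, candidates, outcome = "outcome",
                              log_transform = TRUE) {
  subsets <- enumerate_valid_subsets(candidates)
  fits <- lapply(seq_len(nrow(subsets)), function(i)
    fit_effect_set(cohort, candidates[subsets[i, ]], outcome,
                   log_transform))
  search_result(rank_models(fits, subsets), candidates, "exhaustive")
}

#' Genetic-algorithm configuration
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param tournament_k tournament size for parent selection.
#' @param crossover_p probability of uniform crossover (else copy).
#' @param mutation_rate per-bit mutation probability; default 1/L is filled
#'   in at run time when `NULL`.
#' @param elitism number of best chromosomes carried over unchanged.
#' @param top_k number of ranked models to return.
#' @param seed mandatory integer RNG seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, generations = 100, tournament_k = 3,
                      crossover_p = 0.9, mutation_rate = NULL, elitism = 2,
                      top_k = 10, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("ga_config requires an integer seed", call. = FALSE)
  structure(list(pop_size = pop_size, generations = generations,
                 tournament_k = tournament_k, crossover_p = crossover_p,
                 mutation_rate = mutation_rate, elitism = elitism,
                 top_k = top_k, seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm search for the best-BIC effect subset
#'
#' Evolves marginality-respecting inclusion vectors with tournament
#' selection, uniform crossover, per-bit mutation and elitism; a repair
#' operator drops orphan interactions after every variation step. Fitness is
#' -BIC; fits are cached by inclusion vector, so small candidate spaces cost
#' at most one fit per distinct model. The initial population contains the
#' intercept-only and the (repaired) full chromosome. Deterministic given
#' the config seed.
#'
#' @param cohort a [cohort_table()].
#' @param candidates candidate effects; parents of every candidate
#'   interaction must themselves be candidates.
#' @param config a [ga_config()].
#' @param outcome outcome column name.
#' @param log_transform log-transform concentrations before fitting?
#' @return A `model_search_result` with `method = "ga"`, the best BIC per
#'   generation in `trace`, and the top-k distinct evaluated models ranked
#'   by BIC.
#' @export
ga_search <- function(cohort, candidates, config, outcome = "outcome",
                      log_transform = TRUE) {
  stopifnot(inherits(config, "ga_config"))
  L <- length(candidates)
  for (ef in candidates[vapply(candidates, is_interaction, logical(1))]) {
    p <- effect_parents(ef)
    if (!all(p %in% candidates))
      stop("interaction '", ef, "' lacks candidate main effect(s)",
           call. = FALSE)
  }
  if (L == 0) {
    fit <- fit_effect_set(cohort, character(), outcome, log_transform)
    return(search_result(list(fits = list(fit),
                              inclusions = matrix(logical(0), nrow = 1),
                              bic = fit$bic),
                         candidates, "ga", trace = fit$bic,
                         seed = config$seed, config = config))
  }
  if (L <= 15 && nrow(enumerate_valid_subsets(candidates)) < config$pop_size)
    stop("fewer hierarchy-valid chromosomes than pop_size; shrink the ",
         "population or widen the candidate space", call. = FALSE)
  mu <- if (is.null(config$mutation_rate)) 1 / L else config$mutation_rate

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(inc) {
    key <- paste(as.integer(inc), collapse = "")
    if (is.null(cache[[key]]))
      cache[[key]] <- fit_effect_set(cohort, candidates[inc], outcome,
                                     log_transform)
    cache[[key]]$bic
  }

  pop <- c(list(rep(FALSE, L),
                repair_marginality(rep(TRUE, L), candidates)),
           replicate(config$pop_size - 2,
                     repair_marginality(stats::runif(L) < 0.5, candidates),
                     simplify = FALSE))
  trace <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    fitness <- -vapply(pop, evaluate, numeric(1))
    ord <- order(fitness, decreasing = TRUE)
    trace[gen] <- -fitness[ord[1]]
    elite <- pop[ord[seq_len(config$elitism)]]
    tournament <- function() {
      idx <- sample.int(length(pop), config$tournament_k, replace = TRUE)
      pop[[idx[which.max(fitness[idx])]]]
    }
    offspring <- lapply(seq_len(config$pop_size - config$elitism),
                        function(i) {
      p1 <- tournament(); p2 <- tournament()
      child <- if (stats::runif(1) < config$crossover_p) {
        mask <- stats::runif(L) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      flip <- stats::runif(L) < mu
      repair_marginality(xor(child, flip), candidates)
    })
    pop <- c(elite, offspring)
  }
  # final ranking over every distinct model evaluated
  keys <- ls(cache)
  incs <- t(vapply(keys, function(k)
    as.logical(as.integer(strsplit(k, "")[[1]])), logical(L)))
  colnames(incs) <- candidates
  fits <- lapply(keys, function(k) cache[[k]])
  ranked <- rank_models(fits, incs)
  keep <- seq_len(min(config$top_k, length(ranked$fits)))
  ranked <- list(fits = ranked$fits[keep],
                 inclusions = ranked$inclusions[keep, , drop = FALSE],
                 bic = ranked$bic[keep])
  search_result(ranked, candidates, "ga", trace = trace,
                seed = config$seed, config = config)
}

#' Pearson correlation with a regression line
#'
#' Two-sided p from the t transform `t = r sqrt((n-2)/(1-r^2))`;
#' least-squares slope and intercept of y on x. Pairwise complete cases.
#'
#' @param x,y numeric vectors.
#' @return List with `r`, `p`, `n`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(x, y) {
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  slope <- stats::cov(x, y) / stats::var(x)
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n,
       slope = slope, intercept = mean(y) - slope * mean(x))
}
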