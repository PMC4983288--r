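#' ANOVA-adjusted accession means
#'
#' Fits the additive two-way fixed-effects model
#' `value ~ accession + environment` by least squares and returns, per
#' accession, the least-squares (adjusted) mean: the model prediction
#' averaged over all environments. On a complete balanced design these
#' equal the raw accession means; on unbalanced designs they correct
#' for unequal environment representation.
#'
#' @param pheno data.frame with columns `accession`, `value` and
#'   `environment` (long format); rows for other traits may be removed
#'   beforehand or selected with `trait`.
#' @param trait optional: if `pheno` has a `trait` column, keep only
#'   rows with this trait name.
#' @return class `adjusted_means`: data.frame `means` (accession,
#'   adjusted_value), residual variance `sigma2`, the ANOVA table, and
#'   the fitted `lm` object.
#' @export
adjusted_means <- function(pheno, trait = NULL) {
  if (!is.null(trait)) {
    if (!"trait" %in% names(pheno)) stop("pheno has no 'trait' column")
    pheno <- pheno[pheno$trait == trait, , drop = FALSE]
    if (!nrow(pheno)) stop("no rows for trait '", trait, "'")
  }
  need <- c("accession", "value", "environment")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pheno <- pheno[!is.na(pheno$value), , drop = FALSE]
  pheno$accession <- factor(pheno$accession)
  pheno$environment <- factor(pheno$environment)
  if (nlevels(pheno$accession) < 2) stop("need >= 2 accessions")
  fit <- stats::lm(value ~ accession + environment, data = pheno)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; confounded terms: ",
         paste(bad, collapse = ", "))
  }
  grid <- expand.grid(accession = levels(pheno$accession),
                      environment = levels(pheno$environment))
  pred <- stats::predict(fit, newdata = grid)
  adj <- tapply(pred, grid$accession, mean)
  structure(list(
    means = data.frame(accession = names(adj),
                       adjusted_value = as.numeric(adj),
                       stringsAsFactors = FALSE),
    sigma2 = summary(fit)$sigma^2,
    anova = stats::anova(fit),
    fit = fit), class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("adjusted_means:", nrow(x$means), "accessions; residual variance",
      signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' Binarize Fv/Fm values into tolerant/susceptible scores
#'
#' Maximum quantum yield of photosystem II (Fv/Fm) after a freezing
#' assay is bimodal across a panel: damaged plants score near 0,
#' intact plants near the physiological maximum 0.77. Values strictly
#' above the threshold score 1 (tolerant), values at or below it score
#' 0 (susceptible). The scale mid-point 0.38 is the standard cut; 0.6
#' is a stricter cut isolating the most tolerant material.
#'
#' @param values numeric vector of Fv/Fm measurements in [0, 0.77].
#' @param threshold cut point in (0, 0.77); default 0.38.
#' @return integer vector of 0/1 scores.
#' @export
binarize_fvfm <- function(values, threshold = 0.38) {
  stopifnot(length(threshold) == 1, threshold > 0, threshold < 0.77)
  bad <- !is.na(values) & (values < 0 | values > 0.77)
  if (any(bad))
    stop(sum(bad), " Fv/Fm value(s) outside [0, 0.77]; corrupt input")
  as.integer(values > threshold)
}

#' Frost tolerance scores by logistic regression
#'
#' Fits a binomial logistic model with accession and experiment fixed
#' effects to binarized plant survival scores and reports, per
#' accession, the estimated probability that a plant of that accession
#' tolerates the freezing assay — the inverse logit of the accession
#' effect evaluated at the average experiment effect. Accessions whose
#' plants are all tolerant or all susceptible cause complete
#' separation; their probabilities are clamped to
#' `[eps, 1 - eps]` with `eps = 1/(2 * n_plants_for_that_accession)`
#' and flagged.
#'
#' @param scores data.frame with columns `accession`, `experiment` and
#'   `score` (0/1 per plant). A `condition` column, if present, can be
#'   used to subset via `condition`.
#' @param condition optional label: keep only rows whose `condition`
#'   matches ("optimal" / "sub-optimal"); default uses all rows
#'   ("overall").
#' @param threshold the binarization threshold the scores came from
#'   (recorded in the output, not used in the fit).
#' @return class `frost_scores`: data.frame with `accession`, `score`
#'   (probability in (0,1)), `condition`, `threshold`, `separation`.
#' @export
frost_scores <- function(scores, condition = NULL, threshold = NA_real_) {
  need <- c("accession", "experiment", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cond_label <- "overall"
  if (!is.null(condition)) {
    if (!"condition" %in% names(scores))
      stop("scores has no 'condition' column to subset on")
    scores <- scores[scores$condition == condition, , drop = FALSE]
    if (!nrow(scores)) stop("no rows for condition '", condition, "'")
    cond_label <- condition
  }
  if (!all(scores$score %in% c(0L, 1L)))
    stop("scores must be binary 0/1")
  scores$accession <- factor(scores$accession)
  scores$experiment <- factor(scores$experiment)
  if (nlevels(scores$accession) < 2) stop("need >= 2 accessions")
  ## accession x experiment binomial totals (same likelihood as
  ## plant-level Bernoulli, far fewer rows)
  agg <- stats::aggregate(score ~ accession + experiment, data = scores,
                          FUN = function(z) c(k = sum(z), n = length(z)))
  k <- agg$score[, "k"]; n <- agg$score[, "n"]
  dat <- data.frame(accession = agg$accession, experiment = agg$experiment,
                    k = k, nk = n - k)
  form <- if (nlevels(dat$experiment) > 1)
    cbind(k, nk) ~ accession + experiment else cbind(k, nk) ~ accession
  fit <- suppressWarnings(stats::glm(
    form, family = stats::binomial(), data = dat,
    control = stats::glm.control(maxit = 100)))
  cf <- stats::coef(fit)
  acc <- levels(dat$accession)
  exp_lev <- levels(dat$experiment)
  acc_eff <- c(0, cf[paste0("accession", acc[-1])])
  exp_eff <- c(0, if (length(exp_lev) > 1)
    cf[paste0("experiment", exp_lev[-1])] else NULL)
  eta <- cf["(Intercept)"] + acc_eff + mean(exp_eff)
  p <- stats::plogis(eta)
  ## separation: accession totals at either boundary
  tot_k <- tapply(dat$k, dat$accession, sum)[acc]
  tot_n <- tapply(dat$k + dat$nk, dat$accession, sum)[acc]
  sep <- tot_k == 0 | tot_k == tot_n
  eps <- 1 / (2 * tot_n)
  p <- pmin(pmax(p, eps), 1 - eps)
  structure(list(
    table = data.frame(accession = acc, score = unname(p),
                       condition = cond_label, threshold = threshold,
                       separation = unname(sep), stringsAsFactors = FALSE),
    fit = fit), class = "frost_scores")
}

#' @export
print.frost_scores <- function(x, ...) {
  cat("frost_scores (", x$table$condition[1], "): ",
      nrow(x$table), " accessions, ", sum(x$table$separation),
      " with separation\n", sep = "")
  invisible(x)
}
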