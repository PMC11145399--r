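#' Score a bulk cohort with a gene signature
#'
#' Per-sample enrichment score of the signature via the same kernel-CDF
#' random-walk statistic used for cells ([gsva_scores()]), with bulk
#' samples as columns.
#'
#' @param expr an [ExpressionMatrix()] of bulk expression
#'   (genes x samples, FPKM-like or log scale).
#' @param signature a [top_n_signature()] `Signature` or a character
#'   vector of gene ids (>= 3 measured genes required).
#' @return named numeric vector of per-sample scores.
#' @export
score_bulk <- function(expr, signature) {
  genes <- if (inherits(signature, "Signature")) signature$genes else
    as.character(signature)
  nm <- if (inherits(signature, "Signature")) signature$name else "signature"
  measured <- intersect(genes, rownames(expr$values))
  if (length(measured) < 3L)
    stop("fewer than 3 signature genes measured in the bulk matrix")
  pc <- PathwayCollection(stats::setNames(list(measured), nm))
  sc <- gsva_scores(expr, pc)
  stats::setNames(as.numeric(sc$scores[1L, ]), colnames(sc$scores))
}

#' Build a survival cohort table
#'
#' @param score named per-sample signature score.
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @param covariates optional data.frame of per-sample covariates.
#' @return data.frame of class `SurvivalCohort`.
#' @export
survival_cohort <- function(score, time, event, covariates = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (any(is.na(score))) stop("missing scores are not allowed")
  df <- data.frame(sample_id = names(score) %||% seq_along(score),
                   score = as.numeric(score), time = as.numeric(time),
                   event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  class(df) <- c("SurvivalCohort", "data.frame")
  df
}

# standardized two-group log-rank statistic (signed z): sum over event
# times of (O - E) in group "high", with hypergeometric variance
logrank_z <- function(time, event, high) {
  ev_times <- sort(unique(time[event == 1]))
  O_E <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & high)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & high)
    if (n < 2L) next
    e1 <- d * n1 / n
    v1 <- d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    O_E <- O_E + (d1 - e1)
    V <- V + v1
  }
  if (V <= 0) return(list(z = 0, o_minus_e = O_E, var = V))
  list(z = O_E / sqrt(V), o_minus_e = O_E, var = V)
}

#' Maximally selected survival cutpoint on a signature score
#'
#' Candidate cutpoints are the observed score values leaving at least
#' `minprop` of the cohort on each side; for each candidate the
#' standardized two-group log-rank statistic (score > cutpoint vs rest)
#' is computed, and the cutpoint maximizing its absolute value is
#' returned (ties broken toward the lower cutpoint). Because the
#' statistic is maximized over many candidate splits, the naive log-rank
#' p at the selected cutpoint is optimistic; an optional permutation of
#' the scores (`n_perm_adjust > 0`) yields a selection-adjusted p for
#' the maximal statistic.
#'
#' @param cohort a [survival_cohort()] (columns score, time, event).
#' @param minprop minimum fraction of samples per group (default 0.1).
#' @param n_perm_adjust permutations for the selection-adjusted p
#'   (0 = skip).
#' @param seed seed for the permutation null.
#' @return object of class `CutpointResult`: list with `cutpoint`,
#'   `statistic` (|z| at the cutpoint), `z`, `group_sizes`, `minprop`,
#'   `candidates`, `p_adjusted` (NA unless permuted).
#' @export
optimal_cutpoint <- function(cohort, minprop = 0.1, n_perm_adjust = 0L,
                             seed = 1L) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  s <- sort(unique(df$score))
  lo <- ceiling(minprop * n); hi <- n - lo
  cand <- s[vapply(s, function(c0) {
    k <- sum(df$score > c0); k >= lo && (n - k) >= lo
  }, TRUE)]
  if (!length(cand)) stop("no candidate cutpoint satisfies minprop")
  zs <- vapply(cand, function(c0)
    logrank_z(df$time, df$event, df$score > c0)$z, 0)
  best <- which.max(abs(zs))  # which.max takes the first = lowest cutpoint
  max_obs <- abs(zs[best])
  p_adj <- NA_real_
  if (n_perm_adjust > 0L) {
    set.seed(seed)
    null_max <- vapply(seq_len(n_perm_adjust), function(b) {
      sp <- sample(df$score)
      max(abs(vapply(cand, function(c0)
        logrank_z(df$time, df$event, sp > c0)$z, 0)))
    }, 0)
    p_adj <- (1 + sum(null_max >= max_obs)) / (1 + n_perm_adjust)
  }
  structure(list(cutpoint = cand[best], statistic = max_obs, z = zs[best],
                 group_sizes = c(high = sum(df$score > cand[best]),
                                 low = sum(df$score <= cand[best])),
                 minprop = minprop, candidates = cand,
                 candidate_z = zs, p_adjusted = p_adj),
            class = "CutpointResult")
}

#' @exportS3Method base::print
print.CutpointResult <- function(x, ...) {
  cat(sprintf("CutpointResult: cutpoint %.4g, |z| = %.3f (n = %d high / %d low)\n",
              x$cutpoint, x$statistic, x$group_sizes["high"],
              x$group_sizes["low"]))
  if (!is.na(x$p_adjusted))
    cat(sprintf("selection-adjusted p = %.4g\n", x$p_adjusted))
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' Product-limit survival estimates per group and the two-group log-rank
#' test (observed minus expected events with hypergeometric variance at
#' each event time; p from chi-square with 1 df). A group without events
#' is flagged; a cohort with no events at all yields an undefined
#' statistic with an explicit flag.
#'
#' @param cohort a [survival_cohort()].
#' @param group per-sample two-level labels (e.g. score > cutpoint);
#'   defaults to `score > cutpoint` when `cutpoint` is given.
#' @param cutpoint optional score threshold defining the groups.
#' @return list: `fit` (a [survival::survfit] object), `o_minus_e`,
#'   `chisq`, `p`, `flags`.
#' @export
km_logrank <- function(cohort, group = NULL, cutpoint = NULL) {
  df <- as.data.frame(cohort)
  if (is.null(group)) {
    if (is.null(cutpoint)) stop("supply group labels or a cutpoint")
    group <- ifelse(df$score > cutpoint, "high", "low")
  }
  group <- as.character(group)
  if (length(unique(group)) != 2L) stop("exactly two non-empty groups required")
  flags <- character(0)
  if (sum(df$event) == 0L) {
    flags <- "no events: log-rank statistic undefined"
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    return(list(fit = fit, o_minus_e = NA_real_, chisq = NA_real_,
                p = NA_real_, flags = flags))
  }
  for (g in unique(group))
    if (sum(df$event[group == g]) == 0L)
      flags <- c(flags, paste0("group '", g, "' has no events"))
  lr <- logrank_z(df$time, df$event, group == sort(unique(group))[1L])
  chisq <- if (lr$var > 0) lr$o_minus_e^2 / lr$var else NA_real_
  p <- if (is.na(chisq)) NA_real_ else stats::pchisq(chisq, 1L,
                                                     lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(fit = fit, o_minus_e = lr$o_minus_e, chisq = chisq, p = p,
       flags = flags)
}

#' Multivariate Cox proportional-hazards model
#'
#' Partial-likelihood fit with the Efron approximation for ties. The
#' signature score enters continuously (`score_as = "continuous"`) or as
#' the high/low cutpoint group. Constant covariates are dropped with a
#' warning; duplicated (aliased) covariates raise an error. A warning is
#' emitted when events are fewer than 10 per covariate.
#'
#' @param cohort a [survival_cohort()].
#' @param covariates character vector of covariate column names.
#' @param score_as `"continuous"` or `"group"`.
#' @param cutpoint required when `score_as = "group"`.
#' @return data.frame: term, coef, hr, hr_lower, hr_upper, p; attribute
#'   `"fit"` carries the [survival::coxph] object.
#' @export
cox_multivariate <- function(cohort, covariates = character(0),
                             score_as = c("continuous", "group"),
                             cutpoint = NULL) {
  score_as <- match.arg(score_as)
  df <- as.data.frame(cohort)
  if (score_as == "group") {
    if (is.null(cutpoint)) stop("cutpoint required for score_as = 'group'")
    df$score_group <- factor(ifelse(df$score > cutpoint, "high", "low"),
                             levels = c("low", "high"))
    score_term <- "score_group"
  } else score_term <- "score"
  keep <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(df)) stop("covariate not in cohort: ", cv)
    x <- df[[cv]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("constant covariate dropped: ", cv)
    } else keep <- c(keep, cv)
  }
  terms <- c(score_term, keep)
  n_events <- sum(df$event)
  if (n_events < 10L * length(terms))
    warning(sprintf("only %d events for %d covariates (< 10 per covariate)",
                    n_events, length(terms)))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient model: aliased covariate(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    hr_lower = sm$conf.int[, "lower .95"],
                    hr_upper = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}
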