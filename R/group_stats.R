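#' Fit a mass-by-sex linear mixed model for one kinematic variable
#'
#' Fits `response ~ body_mass + sex (+ body_mass:sex)` with a random
#' intercept per subject, by maximum likelihood (not REML, so that AIC
#' comparisons between models differing in fixed effects are valid).
#' Responses are natural-log transformed by default, the usual scale for
#' positive kinematic magnitudes; the transformation used is recorded in
#' the fit. Fixed-effect t/F tests use the Satterthwaite
#' denominator-degrees-of-freedom approximation.
#'
#' @param records Data.frame of per-jump records with columns
#'   `subject_id`, `sex`, `body_mass` and the response variable. Repeated
#'   rows per subject (multiple jumps) are expected; mass is constant
#'   within subject.
#' @param response Name of the response column.
#' @param with_interaction Include the `body_mass:sex` interaction.
#' @param log_transform Natural-log transform the response.
#' @return An object of class `lmm_fit`: `coef` (estimate, s.e., df, t,
#'   p), `anova` (Type III F table, Satterthwaite), `var_subject`,
#'   `var_residual`, `logLik`, `AIC`, `n_param`, `response`,
#'   `with_interaction`, `log_transform`, `ddf_method`, and the
#'   underlying `model`.
#' @export
fit_lmm <- function(records, response, with_interaction = FALSE,
                    log_transform = TRUE) {
  need <- c("subject_id", "sex", "body_mass", response)
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("records missing column(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
  df <- records
  df$sex <- factor(df$sex, levels = c("female", "male"))
  if (nlevels(droplevels(df$sex)) < 2) {
    stop("singular design: both sexes are required", call. = FALSE)
  }
  if (length(unique(df$subject_id)) < 4) {
    stop("need at least 2 subjects per sex", call. = FALSE)
  }
  df$.y <- df[[response]]
  if (log_transform) {
    if (any(df$.y <= 0, na.rm = TRUE)) {
      stop("log transform requested but response has non-positive values",
           call. = FALSE)
    }
    df$.y <- log(df$.y)
  }
  rhs <- if (with_interaction) "body_mass * sex" else "body_mass + sex"
  form <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | subject_id)"))
  model <- lmerTest::lmer(form, data = df, REML = FALSE)
  smry <- summary(model, ddf = "Satterthwaite")
  co <- as.data.frame(smry$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")
  co$term <- rownames(co); rownames(co) <- NULL
  co <- co[, c("term", "estimate", "se", "df", "t", "p")]
  an <- as.data.frame(stats::anova(model, type = 3, ddf = "Satterthwaite"))
  an$term <- rownames(an); rownames(an) <- NULL
  vc <- as.data.frame(lme4::VarCorr(model))
  var_subject <- vc$vcov[vc$grp == "subject_id"]
  var_residual <- vc$vcov[vc$grp == "Residual"]
  ll <- as.numeric(stats::logLik(model))
  k <- attr(stats::logLik(model), "df")
  structure(list(coef = co, anova = an, var_subject = var_subject,
                 var_residual = var_residual, logLik = ll,
                 AIC = 2 * k - 2 * ll, n_param = k,
                 response = response, with_interaction = with_interaction,
                 log_transform = log_transform,
                 ddf_method = "Satterthwaite", model = model),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("lmm_fit: %s%s ~ body_mass %s sex + (1|subject), ML\n",
              if (x$log_transform) "log " else "", x$response,
              if (x$with_interaction) "*" else "+"))
  print(x$coef, digits = 3)
  cat(sprintf("subject var %.4g, residual var %.4g, AIC %.2f (%s ddf)\n",
              x$var_subject, x$var_residual, x$AIC, x$ddf_method))
  invisible(x)
}

#' Select between the interaction and additive mixed models by AIC
#'
#' Returns the fit with the lower AIC; on a numerical tie the reduced
#' (additive) model wins by parsimony.
#'
#' @param fit_full [fit_lmm()] with the interaction.
#' @param fit_reduced [fit_lmm()] without it.
#' @return List with `selected` (an `lmm_fit`), `which` (`"full"` or
#'   `"reduced"`), `delta_aic` (`AIC_full - AIC_reduced`).
#' @export
select_model <- function(fit_full, fit_reduced) {
  if (!identical(fit_full$response, fit_reduced$response) ||
      !identical(fit_full$log_transform, fit_reduced$log_transform)) {
    stop("model comparison error: fits are not for the same response",
         call. = FALSE)
  }
  d <- fit_full$AIC - fit_reduced$AIC
  if (d < -1e-9) {
    list(selected = fit_full, which = "full", delta_aic = d)
  } else {
    list(selected = fit_reduced, which = "reduced", delta_aic = d)
  }
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank ties.
#' `U` is the smaller of the two group statistics. The p-value is exact
#' (permutation enumeration of the rank assignment) for combined sample
#' sizes up to 20, and a normal approximation with tie correction and
#' continuity correction otherwise. Two-sided.
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `p_value`, `method`, `U_a`, `U_b`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("empty group", call. = FALSE)
  r <- rank(c(a, b))
  U_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_b <- n1 * n2 - U_a
  U <- min(U_a, U_b)
  N <- n1 + n2
  if (N <= 20) {
    # exact permutation distribution of U_a over all C(N, n1) labelings
    idx <- utils::combn(N, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    U_perm <- sums - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(U_perm <= U_a), mean(U_perm >= U_a))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sd_u <- sqrt(n1 * n2 / 12 * (N + 1 - tie_term))
    z <- (abs(U_a - mu) - 0.5) / sd_u
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method, U_a = U_a, U_b = U_b)
}
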