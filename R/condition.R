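#' Fulton's condition factor
#'
#' `K = 100 * weight / length^3` with weight in grams and standard length in
#' cm; around 1-2 for salmonids in reasonable condition.
#'
#' @param weight mass in grams (> 0).
#' @param length standard length in cm (> 0).
#' @return numeric vector of condition factors.
#' @export
fulton_k <- function(weight, length) {
  if (any(!is.finite(weight)) || any(!is.finite(length)) ||
      any(weight <= 0) || any(length <= 0))
    stop("weight and length must be positive")
  100 * weight / length^3
}

#' MHC frequency index per individual
#'
#' Sum of the within-population frequencies of the one or two MHC variants an
#' individual carries (a homozygote scores twice the frequency of its single
#' variant). Carriers of locally rare variants get low values; the index is
#' bounded by 2. The focal individual is included in the frequency estimate
#' by default; `leave_one_out = TRUE` excludes its own two gene copies.
#'
#' @param table a [genotype_table()] (allele or supertype space).
#' @param leave_one_out exclude the focal individual's copies.
#' @return numeric vector aligned with the rows of `table`.
#' @export
mhc_frequency_index <- function(table, leave_one_out = FALSE) {
  fl <- freq_list(table, "MHC")
  if (!leave_one_out)
    return(vapply(seq_len(nrow(table)), function(i) {
      f <- fl[[table$population[i]]]
      unname(f[table$mhc_1[i]] + f[table$mhc_2[i]])
    }, 0))
  af <- allele_frequencies(table, "MHC")
  vapply(seq_len(nrow(table)), function(i) {
    d <- af[af$population == table$population[i], ]
    tot <- sum(d$count) - 2L
    if (table$mhc_1[i] == table$mhc_2[i]) {
      2 * (d$count[match(table$mhc_1[i], d$allele)] - 2L) / tot
    } else {
      (d$count[match(table$mhc_1[i], d$allele)] - 1L +
         d$count[match(table$mhc_2[i], d$allele)] - 1L) / tot
    }
  }, 0)
}

#' Residualize one predictor on another (sequential regression)
#'
#' Linear: ordinary least-squares residuals. Binomial: response residuals
#' (observed 0/1 minus fitted probability) from a logistic fit; `"deviance"`
#' residuals are available behind the `type` flag.
#'
#' @param response numeric (linear) or 0/1 (binomial) vector.
#' @param predictor numeric vector.
#' @param family `"linear"` or `"binomial"`.
#' @param type binomial residual type, `"response"` (default) or
#'   `"deviance"`.
#' @return numeric residual vector.
#' @export
residualize <- function(response, predictor, family = c("linear",
                                                        "binomial"),
                        type = c("response", "deviance")) {
  family <- match.arg(family); type <- match.arg(type)
  if (length(response) != length(predictor)) stop("length mismatch")
  if (stats::sd(predictor) == 0) stop("constant predictor")
  if (family == "linear")
    return(unname(stats::resid(stats::lm(response ~ predictor))))
  fit <- stats::glm(response ~ predictor, family = stats::binomial())
  unname(stats::residuals(fit, type = type))
}

#' Assemble per-individual condition-model records
#'
#' Builds the predictor set for the body-condition mixed models: Fulton's K,
#' the MHC frequency index and zygosity in allele space (and supertype space
#' when a clustering solution is given), the zygosity residualized on the
#' frequency index (binomial response residuals), the within-genotype
#' sequence dissimilarities (0 for homozygotes; requires the catalogue),
#' the proportion of heterozygous STR loci over non-missing loci, and the
#' LDH type factor (reference level `"domestic"` = 90/90).
#'
#' @param table a [genotype_table()] in allele space.
#' @param catalog optional [allele_catalog()] for sequence dissimilarity.
#' @param solution optional `cluster_solution` for supertype-space fields.
#' @param leave_one_out passed to [mhc_frequency_index()].
#' @return data.frame of class `condition_records`.
#' @export
condition_records <- function(table, catalog = NULL, solution = NULL,
                              leave_one_out = FALSE) {
  rec <- data.frame(id = table$id, population = table$population,
                    K = fulton_k(table$weight, table$length),
                    stringsAsFactors = FALSE)
  rec$freq_index <- mhc_frequency_index(table, leave_one_out)
  rec$zygosity <- as.integer(table$mhc_1 != table$mhc_2)
  rec$zygosity_resid <- residualize(rec$zygosity, rec$freq_index,
                                    family = "binomial")
  if (!is.null(solution)) {
    st <- genotypes_to_supertypes(table, solution)
    rec$freq_index_st <- mhc_frequency_index(st, leave_one_out)
    rec$zygosity_st <- as.integer(st$mhc_1 != st$mhc_2)
    rec$zygosity_st_resid <- residualize(rec$zygosity_st, rec$freq_index_st,
                                         family = "binomial")
  }
  if (!is.null(catalog)) {
    d <- sequence_dissimilarity(catalog, table$mhc_1, table$mhc_2)
    rec$mhc_dissim_nt <- d$d_nt
    rec$mhc_dissim_aa <- d$d_aa
  }
  loci <- str_loci(table)
  het <- vapply(seq_len(nrow(table)), function(i) {
    h <- vapply(loci, function(l) {
      a <- table[[paste0(l, "_1")]][i]; b <- table[[paste0(l, "_2")]][i]
      if (is.na(a) || is.na(b)) NA else as.numeric(a != b)
    }, 0)
    mean(h, na.rm = TRUE)
  }, 0)
  rec$str_het <- het
  rec$ldh_type <- factor(
    ifelse(table$ldh_1 == "100" & table$ldh_2 == "100", "native",
           ifelse(table$ldh_1 == "90" & table$ldh_2 == "90", "domestic",
                  "hybrid")),
    levels = c("domestic", "hybrid", "native"))
  class(rec) <- c("condition_records", "data.frame")
  rec
}

condition_formula <- function(model) {
  switch(model,
    "1_DAB" = K ~ freq_index + zygosity_resid + str_het + ldh_type +
      (1 | population),
    "1_ST" = K ~ freq_index_st + zygosity_st_resid + str_het + ldh_type +
      (1 | population),
    "2_NU" = K ~ mhc_dissim_nt + str_het + ldh_type + (1 | population),
    "2_AA" = K ~ mhc_dissim_aa + str_het + ldh_type + (1 | population),
    stop("unknown model: ", model))
}

#' Fit a body-condition mixed model
#'
#' Linear mixed model of Fulton's K on MHC predictors with a population
#' random intercept; model `1_*` tests rare-allele advantage (frequency
#' index) and heterozygote advantage (residualized zygosity), model `2_*`
#' tests divergent-allele advantage (sequence dissimilarity). Coefficients
#' come from the REML fit with Satterthwaite denominator degrees of freedom
#' (computed from the curvature of the restricted likelihood in the two
#' variance parameters); AICc is evaluated on an ML refit. If the random
#' intercept variance collapses to the boundary, the model falls back to a
#' fixed-intercept linear model and flags it.
#'
#' @param records a [condition_records()] data.frame.
#' @param model `"1_DAB"`, `"1_ST"`, `"2_NU"` or `"2_AA"`, or a custom
#'   `lme4` formula.
#' @param df_method `"satterthwaite"` (default) or `"residual"`.
#' @return list of class `fit_result`: `model_id`, `coefficients`
#'   (data.frame estimate/SE/df/t/p), `varcomp` (population, residual),
#'   `R2_marginal`, `R2_conditional`, `AICc`, `logLik_ML`, `n`, `singular`.
#' @export
fit_condition_model <- function(records, model = "1_DAB",
                                df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  form <- if (inherits(model, "formula")) model else condition_formula(model)
  model_id <- if (inherits(model, "formula")) deparse(form) else model
  fit <- suppressMessages(lme4::lmer(form, data = records, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular)
    warning("random-intercept variance is on the boundary; ",
            "coefficients fall back to a fixed-intercept linear model")
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_pop <- vc$vcov[vc$grp == "population"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  X <- stats::model.matrix(fit)
  n <- nrow(X); p <- ncol(X)
  if (singular) {
    lmfit <- stats::lm(lme4::nobars(form), data = records)
    sm <- summary(lmfit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                        SE = sm[, 2L], df = lmfit$df.residual,
                        t = sm[, 3L], p = sm[, 4L], row.names = NULL,
                        stringsAsFactors = FALSE)
  } else {
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    dfs <- if (df_method == "satterthwaite")
      satterthwaite_df(fit, X, records) else rep(n - p, p)
    tval <- beta / se
    coefs <- data.frame(term = names(beta), estimate = unname(beta),
                        SE = unname(se), df = dfs, t = unname(tval),
                        p = 2 * stats::pt(abs(tval), dfs,
                                          lower.tail = FALSE),
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  var_fix <- stats::var(as.vector(X %*% beta))
  tot <- var_fix + var_pop + var_res
  ml <- suppressMessages(lme4::refitML(fit))
  k <- p + 2L
  aicc <- stats::AIC(ml) + 2 * k * (k + 1) / (n - k - 1)
  structure(list(model_id = model_id, coefficients = coefs,
                 varcomp = c(population = var_pop, residual = var_res),
                 R2_marginal = var_fix / tot,
                 R2_conditional = (var_fix + var_pop) / tot,
                 AICc = aicc, logLik_ML = as.numeric(stats::logLik(ml)),
                 n = n, singular = singular, fit = fit),
            class = "fit_result")
}

# Satterthwaite denominator df for each fixed effect of a single
# random-intercept lmer fit. The restricted log-likelihood is re-expressed
# in the two variance components (vu, ve); the asymptotic covariance of
# their estimates is the inverse curvature (numerical Hessian) of the
# -2*logLik(REML) surface divided by 2, and the df for contrast c follows
# from df = 2 * (c' C c)^2 / Var(c' C c) with the delta method.
satterthwaite_df <- function(fit, X, data) {
  grp <- factor(fit@frame$population)
  Z <- stats::model.matrix(~ 0 + grp)
  y <- stats::model.response(fit@frame)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vu <- max(vc$vcov[vc$grp == "population"], 1e-10)
  ve <- vc$vcov[vc$grp == "Residual"]
  n <- nrow(X); p <- ncol(X)
  ZZt <- tcrossprod(Z)
  Cbeta <- function(v) {
    V <- v[1L] * ZZt + diag(v[2L], n)
    Vi <- chol2inv(chol(V))
    list(C = solve(crossprod(X, Vi %*% X)), Vi = Vi)
  }
  m2ll <- function(v) {
    V <- v[1L] * ZZt + diag(v[2L], n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    C <- solve(XtVi %*% X)
    b <- C %*% (XtVi %*% y)
    r <- y - X %*% b
    2 * sum(log(diag(ch))) + determinant(XtVi %*% X)$modulus +
      as.numeric(crossprod(r, Vi %*% r))
  }
  v0 <- c(vu, ve)
  h <- pmax(1e-6, abs(v0) * 1e-4)
  H <- matrix(0, 2L, 2L)
  for (a in 1:2) for (b in 1:2) {
    ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
    H[a, b] <- (m2ll(v0 + ea + eb) - m2ll(v0 + ea - eb) -
                m2ll(v0 - ea + eb) + m2ll(v0 - ea - eb)) /
      (4 * h[a] * h[b])
  }
  cov_v <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_v) || any(!is.finite(cov_v)))
    return(rep(n - p, p))
  f0 <- diag(Cbeta(v0)$C)
  grad <- matrix(0, 2L, p)
  for (a in 1:2) {
    ea <- c(0, 0); ea[a] <- h[a]
    grad[a, ] <- (diag(Cbeta(v0 + ea)$C) - diag(Cbeta(v0 - ea)$C)) /
      (2 * h[a])
  }
  dfs <- vapply(seq_len(p), function(j) {
    vf <- as.numeric(crossprod(grad[, j], cov_v %*% grad[, j]))
    if (vf <= 0) return(n - p)
    2 * f0[j]^2 / vf
  }, 0)
  pmin(pmax(dfs, 1), n - p)
}

#' @method print fit_result
#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model_id, " (n = ", x$n, ")\n", sep = "")
  print(transform(x$coefficients, estimate = signif(estimate, 3),
                  SE = signif(SE, 3), df = round(df, 1),
                  t = round(t, 2), p = signif(p, 2)))
  cat(sprintf("R2m = %.3f, R2c = %.3f, AICc = %.2f\n",
              x$R2_marginal, x$R2_conditional, x$AICc))
  invisible(x)
}

#' Across-population richness models with sequential regression
#'
#' Models MHC allelic (and supertype) richness on neutral STR richness and
#' lineage admixture at the diagnostic LDH locus. Both predictors are
#' z-scored; the admixture predictor is then residualized on STR richness
#' (ordinary least squares) and re-standardized, so its coefficient measures
#' the admixture effect net of neutral diversity while staying on a
#' unit-variance scale.
#'
#' @param summary_df data.frame with one row per population and columns
#'   `population`, `str_richness`, `mhc_dab_richness`, `mhc_st_richness`
#'   (optional), `ldh_admixture` (frequency of the less common LDH allele;
#'   proportion or percent, the scaling cancels).
#' @return list with elements `dab` and (when present) `st`, each a list
#'   with `coefficients` (estimate/SE/t/p), `adj_r_squared`, `n`; plus
#'   `collinearity` (Spearman correlation between STR richness and
#'   admixture).
#' @export
fit_richness_models <- function(summary_df) {
  need <- c("population", "str_richness", "mhc_dab_richness",
            "ldh_admixture")
  miss <- setdiff(need, names(summary_df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(summary_df) < 4L) stop("need at least 4 populations")
  zs <- function(x) {
    if (stats::sd(x) == 0) stop("constant predictor")
    as.numeric(scale(x))
  }
  str_z <- zs(summary_df$str_richness)
  adm_z <- zs(summary_df$ldh_admixture)
  adm_resid <- zs(residualize(adm_z, str_z, family = "linear"))
  one <- function(y) {
    fit <- stats::lm(y ~ str_z + adm_resid)
    sm <- summary(fit)
    co <- sm$coefficients
    list(coefficients = data.frame(
           term = c("intercept", "str_richness", "ldh_admixture_resid"),
           estimate = co[, 1L], SE = co[, 2L], t = co[, 3L], p = co[, 4L],
           row.names = NULL, stringsAsFactors = FALSE),
         adj_r_squared = sm$adj.r.squared, n = length(y))
  }
  out <- list(dab = one(summary_df$mhc_dab_richness),
              collinearity = stats::cor(summary_df$str_richness,
                                        summary_df$ldh_admixture,
                                        method = "spearman"))
  if ("mhc_st_richness" %in% names(summary_df))
    out$st <- one(summary_df$mhc_st_richness)
  out
}

#' Per-individual supertype presence/absence matrix
#'
#' @param table_st a [genotype_table()] in supertype space (see
#'   [genotypes_to_supertypes()]).
#' @return 0/1 integer matrix, individuals x supertypes.
#' @export
supertype_presence <- function(table_st) {
  sts <- sort(unique(c(table_st$mhc_1, table_st$mhc_2)))
  m <- vapply(sts, function(s)
    as.integer(table_st$mhc_1 == s | table_st$mhc_2 == s),
    integer(nrow(table_st)))
  m <- matrix(m, nrow = nrow(table_st), dimnames = list(table_st$id, sts))
  m
}

#' Supertype-specific condition models ranked by AICc
#'
#' Adds one supertype presence/absence indicator at a time to the baseline
#' supertype-space condition model (model `1_ST`), refits by maximum
#' likelihood, and ranks the candidates by AICc. Models at least 2 AICc
#' points below the baseline are flagged as substantially better; their
#' carrier effects (beta) deserve inspection. Supertypes carried by no one
#' or by everyone are skipped.
#'
#' @param records a [condition_records()] built with a supertype solution.
#' @param presence matrix from [supertype_presence()], rows aligned with
#'   `records`.
#' @param baseline optional `fit_result` for the baseline; refit when
#'   omitted.
#' @return data.frame of class `supertype_scan`: one row per model
#'   (baseline included) with `model`, `df`, `logLik`, `AICc`, `dAICc`,
#'   `beta`, `p`, `N_carriers`, `better`, sorted by AICc.
#' @export
supertype_scan <- function(records, presence, baseline = NULL) {
  base_form <- condition_formula("1_ST")
  fit_ml <- function(form, dat) {
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = FALSE)))
    k <- length(lme4::fixef(m)) + 2L
    n <- stats::nobs(m)
    list(m = m, df = k, ll = as.numeric(stats::logLik(m)),
         aicc = stats::AIC(m) + 2 * k * (k + 1) / (n - k - 1))
  }
  b <- fit_ml(base_form, records)
  rows <- list(data.frame(model = "baseline", df = b$df, logLik = b$ll,
                          AICc = b$aicc, dAICc = 0, beta = NA_real_,
                          p = NA_real_, N_carriers = NA_integer_,
                          stringsAsFactors = FALSE))
  skipped <- character()
  for (s in colnames(presence)) {
    carriers <- sum(presence[, s])
    if (carriers == 0L || carriers == nrow(presence)) {
      skipped <- c(skipped, s)
      next
    }
    dat <- records
    dat$.st <- presence[, s]
    f <- stats::update(base_form, . ~ . + .st)
    fs <- fit_ml(f, dat)
    est <- lme4::fixef(fs$m)[".st"]
    se <- sqrt(diag(as.matrix(stats::vcov(fs$m))))[".st"]
    z <- est / se
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste0("baseline + ", s), df = fs$df, logLik = fs$ll,
      AICc = fs$aicc, dAICc = fs$aicc - b$aicc, beta = unname(est),
      p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      N_carriers = carriers, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  out$better <- !is.na(out$dAICc) & out$dAICc < -2
  attr(out, "skipped") <- skipped
  class(out) <- c("supertype_scan", "data.frame")
  out
}
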