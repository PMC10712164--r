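#' Observed growth rate from an optical-density series
#'
#' Consecutive-pair log slope: `mu_i = ln(OD_{i+1}/OD_i) / (t_{i+1} -
#' t_i)`, assigned to the interval midpoint. Exact on pure exponentials
#' for any sampling grid. An optional 3-point centred rolling mean
#' smooths the estimates.
#'
#' @param time time points (h), strictly increasing.
#' @param od optical density (or any biomass proxy), strictly positive.
#' @param smooth apply a 3-point rolling mean.
#' @return Data frame with `time` (midpoints) and `mu` (1/h).
#' @export
growth_rate <- function(time, od, smooth = FALSE) {
  if (length(time) < 2) stop("need at least two time points")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(od <= 0)) stop("optical density must be strictly positive")
  mu <- diff(log(od)) / diff(time)
  mid <- (time[-1] + time[-length(time)]) / 2
  if (smooth && length(mu) >= 3) {
    sm <- stats::filter(mu, rep(1 / 3, 3), sides = 2)
    mu <- ifelse(is.na(sm), mu, as.numeric(sm))
  }
  data.frame(time = mid, mu = mu)
}

#' Total cell productivity from a dry-weight series
#'
#' Finite-difference productivity `dCDW/dt` per interval, midpoint
#' assigned.
#'
#' @param time time points (h), strictly increasing.
#' @param cdw cell dry weight (g/L).
#' @return Data frame with `time` (midpoints) and `productivity`
#'   (g CDW/L/h).
#' @export
productivity <- function(time, cdw) {
  if (length(time) < 2) stop("need at least two time points")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  data.frame(time = (time[-1] + time[-length(time)]) / 2,
             productivity = diff(cdw) / diff(time))
}

# Theoretical oxygen demand (gCOD per g) from an elemental formula
# CcHhOoNn, nitrogen reduced to ammonia: ThOD = 32*(c + h/4 - o/2 - 3n/4)/MW.
.parse_formula <- function(formula) {
  m <- gregexpr("([CHON])([0-9]*)", formula)[[1]]
  if (m[1] == -1) stop("cannot parse formula: ", formula)
  toks <- regmatches(formula, gregexpr("([CHON])([0-9]*)", formula))[[1]]
  el <- substr(toks, 1, 1)
  n <- as.numeric(sub("^[CHON]", "", toks))
  n[is.na(n)] <- 1
  out <- c(C = 0, H = 0, O = 0, N = 0)
  for (i in seq_along(el)) out[el[i]] <- out[el[i]] + n[i]
  out
}

#' Theoretical COD factor of an organic compound
#'
#' Oxygen demand of complete oxidation (nitrogen to ammonia), in gCOD per
#' g compound, computed from the elemental formula by the oxygen-demand
#' balance. E.g. fructose C6H12O6 gives 192/180 ~ 1.067 gCOD/g.
#'
#' @param formula elemental formula over C, H, O, N (e.g. `"C6H12O6"`).
#' @return gCOD per g compound.
#' @export
cod_factor <- function(formula) {
  e <- .parse_formula(formula)
  mw <- sum(e * c(C = 12.011, H = 1.008, O = 15.999, N = 14.007))
  unname(32 * (e["C"] + e["H"] / 4 - e["O"] / 2 - 3 * e["N"] / 4) / mw)
}

#' Built-in COD conversion factors
#'
#' gCOD per g for common fermentation substrates and metabolites,
#' computed from elemental formulas via [cod_factor()].
#'
#' @return Named numeric vector.
#' @export
cod_factors_builtin <- function() {
  vapply(c(fructose = "C6H12O6", glucose = "C6H12O6", methanol = "CH4O",
           ethanol = "C2H6O", acetate = "C2H4O2", lactate = "C3H6O3",
           glycerol = "C3H8O3", formate = "CH2O2"),
         cod_factor, numeric(1))
}

#' Aggregate organic compounds as chemical oxygen demand
#'
#' Sums compound concentrations weighted by their COD factors and
#' expresses the total both as gCOD/L and as electron equivalents
#' (1 eeq = 8 gCOD).
#'
#' @param concentrations named numeric vector, g compound / L.
#' @param factors named gCOD/g factors; defaults to
#'   [cod_factors_builtin()]. A factor must exist for every compound.
#' @return List with `cod` (gCOD/L) and `eeq` (eeq/L).
#' @export
cod_aggregate <- function(concentrations, factors = cod_factors_builtin()) {
  miss <- setdiff(names(concentrations), names(factors))
  if (length(miss) > 0)
    stop("no COD factor for compound(s): ", paste(miss, collapse = ", "))
  cod <- sum(concentrations * factors[names(concentrations)])
  list(cod = unname(cod), eeq = unname(cod) / 8)
}

#' Classify substrate-limitation phase
#'
#' Labels each sampling point `limiting` when the residual limiting
#' substrate has fallen below a fraction `theta` of its initial
#' concentration AND the growth rate is below `mu_frac` of the run's
#' maximum; otherwise `abundant`. The rule and its parameters are
#' recorded in the result's attributes.
#'
#' @param series a `sample_series` (or data frame with `time`, `COD`,
#'   `NH4`, `mu` columns).
#' @param limitation `"carbon"`, `"nitrogen"` or `"dual"`.
#' @param theta residual-substrate fraction of initial (default 0.10).
#' @param mu_frac growth-rate fraction of the run maximum (default 0.90);
#'   `NULL` disables the growth-rate condition and classifies on residual
#'   substrate alone.
#' @return Character vector of labels (`abundant`/`limiting`) with
#'   attributes `rule`, `theta`, `mu_frac`.
#' @export
classify_phase <- function(series, limitation = c("carbon", "nitrogen", "dual"),
                           theta = 0.10, mu_frac = 0.90) {
  limitation <- match.arg(limitation)
  sub <- switch(limitation,
                carbon = series$COD,
                nitrogen = series$NH4,
                dual = pmin(series$COD / series$COD[1], series$NH4 / series$NH4[1]))
  rel <- if (limitation == "dual") sub else sub / sub[1]
  low_sub <- rel < theta
  slow <- if (is.null(mu_frac)) rep(TRUE, length(low_sub))
          else series$mu < mu_frac * max(series$mu)
  structure(ifelse(low_sub & slow, "limiting", "abundant"),
            rule = "residual < theta * initial AND mu < mu_frac * max(mu)",
            theta = theta,
            mu_frac = if (is.null(mu_frac)) NA_real_ else mu_frac)
}

# Spearman rho with mid-rank ties + two-sided p via the t approximation.
.spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) p <- 0
  else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman correlogram
#'
#' Pairwise Spearman rank correlations (mid-rank ties) over a table of
#' observables, with two-sided p-values from the t approximation and a
#' significance mask at level `alpha`. Missing values are handled by
#' pairwise-complete deletion. No multiplicity correction is applied by
#' default; `adjust = "BH"` applies Benjamini-Hochberg across the
#' off-diagonal pairs.
#'
#' @param data data frame of numeric variables.
#' @param vars variables to correlate (default all numeric columns).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` or `"BH"`.
#' @param stratum label stored with the result.
#' @return A `correlogram`: list of matrices `rho`, `p`, `n`,
#'   `significant`, plus `alpha` and `stratum`.
#' @export
correlogram <- function(data, vars = NULL, alpha = 0.05,
                        adjust = c("none", "BH"), stratum = "all") {
  adjust <- match.arg(adjust)
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  k <- length(vars)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    p[i, i] <- 0
    n[i, i] <- sum(!is.na(data[[vars[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      s <- .spearman(data[[vars[i]]], data[[vars[j]]])
      if (is.na(s["rho"]))
        warning("Spearman rho undefined for ", vars[i], " vs ", vars[j],
                " (constant variable or too few complete pairs)")
      rho[i, j] <- rho[j, i] <- s["rho"]
      p[i, j] <- p[j, i] <- s["p"]
      n[i, j] <- n[j, i] <- s["n"]
    }
  }
  if (adjust == "BH") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(rho = rho, p = p, n = n,
                 significant = !is.na(p) & p < alpha,
                 alpha = alpha, adjust = adjust, stratum = stratum),
            class = "correlogram")
}

#' Stratified correlograms by limitation phase
#'
#' Computes [correlogram()]s for the pooled data and separately for the
#' substrate-abundant and substrate-limiting strata (and per limitation
#' type when a `limitation` column is present).
#'
#' @param data data frame including a `phase` column
#'   (`abundant`/`limiting`) and optionally `limitation`.
#' @param vars variables to correlate.
#' @param ... passed to [correlogram()].
#' @return Named list of `correlogram`s.
#' @export
correlogram_strata <- function(data, vars = NULL, ...) {
  out <- list(all = correlogram(data, vars, stratum = "all", ...))
  if ("phase" %in% names(data)) {
    for (ph in intersect(c("abundant", "limiting"), unique(data$phase)))
      out[[ph]] <- correlogram(data[data$phase == ph, , drop = FALSE],
                               vars, stratum = ph, ...)
  }
  if ("limitation" %in% names(data)) {
    for (lim in unique(data$limitation))
      out[[paste0("limitation_", lim)]] <-
        correlogram(data[data$limitation == lim, , drop = FALSE],
                    vars, stratum = lim, ...)
  }
  out
}

#' @export
print.correlogram <- function(x, digits = 2, ...) {
  cat(sprintf("correlogram (stratum: %s, alpha = %g%s)\n", x$stratum,
              x$alpha, if (x$adjust == "BH") ", BH-adjusted" else ""))
  m <- format(round(x$rho, digits))
  m[x$significant] <- paste0(m[x$significant], "*")
  print(m, quote = FALSE)
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  k <- ncol(x$rho)
  graphics::image(seq_len(k), seq_len(k), t(x$rho[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(21, "Blue-Red 3"),
                  main = paste("Spearman correlogram:", x$stratum), ...)
  graphics::axis(1, seq_len(k), colnames(x$rho), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(rownames(x$rho)), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Write correlograms as a long TSV
#'
#' @param correlograms named list of `correlogram`s.
#' @param path output TSV (stratum, var1, var2, rho, p, n, significant).
#' @return `path`, invisibly.
#' @export
write_correlograms <- function(correlograms, path) {
  rows <- do.call(rbind, lapply(correlograms, function(cg) {
    vars <- rownames(cg$rho)
    idx <- which(upper.tri(cg$rho), arr.ind = TRUE)
    data.frame(stratum = cg$stratum, var1 = vars[idx[, 1]],
               var2 = vars[idx[, 2]], rho = cg$rho[idx], p = cg$p[idx],
               n = cg$n[idx], significant = cg$significant[idx])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Linear fit with pointwise 95% confidence band
#'
#' Ordinary least squares of `y` on `x` with the standard t-based
#' pointwise confidence interval for the mean response, as drawn as the
#' shaded band around trend lines.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @param newx abscissae for the band (default sorted `x`).
#' @param level confidence level (default 0.95).
#' @return List with `slope`, `intercept`, and `band` (data frame `x`,
#'   `fit`, `lwr`, `upr`).
#' @export
linear_fit_ci <- function(x, y, newx = sort(x), level = 0.95) {
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  pred <- stats::predict(fit, newdata = data.frame(x = newx),
                         interval = "confidence", level = level)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       band = data.frame(x = newx, fit = pred[, "fit"],
                         lwr = pred[, "lwr"], upr = pred[, "upr"]))
}

#' Join interval estimates to composition samples by nearest time
#'
#' Growth-rate and productivity estimates live on interval midpoints;
#' composition observables live on sampling times. This matches each
#' sampling time to the nearest midpoint within a tolerance.
#'
#' @param series data frame with a `time` column.
#' @param intervals data frame with `time` plus value columns (e.g. from
#'   [growth_rate()]).
#' @param tolerance maximum time distance (h) for a match (default 1).
#' @return `series` with the interval value columns appended (NA where no
#'   midpoint lies within tolerance).
#' @export
join_nearest_time <- function(series, intervals, tolerance = 1) {
  vals <- setdiff(names(intervals), "time")
  for (v in vals) series[[v]] <- NA_real_
  for (i in seq_len(nrow(series))) {
    d <- abs(intervals$time - series$time[i])
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tolerance)
      for (v in vals) series[[v]][i] <- intervals[[v]][j]
  }
  series
}
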