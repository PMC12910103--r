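.PREDICTORS <- c("temperature", "salinity", "oxygen", "chlorophyll_a", "par")

#' Match echo-integrated backscatter to CTD stations
#'
#' For each station, grid columns within `radius_nmi` (great-circle) are
#' pooled by diel phase, giving up to one day and one night record per
#' station — day and night are both retained so the models see the full
#' range of conditions. Each record's Sv per frequency is the linear-domain
#' mean over the above-threshold cells of the matched columns, and each
#' environmental predictor is the station profile's mean over the depth span
#' of those cells (linear interpolation of the profile at 1 m steps).
#' Stations with no matched column, or matched columns with no
#' above-threshold cell, contribute nothing; if no station matches at all,
#' an error reports the nearest distances.
#'
#' @param g18,g38 [IntegrationGrid]s on a shared timebase.
#' @param stations list of [CTDStation].
#' @param radius_nmi matching radius (nautical miles).
#' @param threshold_db cells at or above this define the layer stratum.
#' @param location optional region code per station; defaults to the prefix
#'   of the station id (before `"-"`).
#' @return data.frame of matched records (one per station x diel phase).
#' @export
matchAcousticToCtd <- function(g18, g38, stations, radius_nmi = 0.1,
                               threshold_db = -70, location = NULL) {
  pos <- pingPositions(g18)
  diel <- .columnDiel(g18)
  if (is.null(location))
    location <- vapply(stations, function(s) sub("-.*$", "", s@station_id),
                       character(1))
  rd <- rowData(g18)
  nearest <- numeric(length(stations))
  records <- list()
  for (si in seq_along(stations)) {
    s <- stations[[si]]
    d <- haversineNmi(s@lat, s@lon, pos$lat, pos$lon)
    nearest[si] <- min(d)
    cols <- which(d <= radius_nmi)
    if (!length(cols)) next
    for (ph in intersect(c("day", "night"), unique(diel[cols]))) {
      pc <- cols[diel[cols] == ph]
      m18 <- svMatrix(g18)[, pc, drop = FALSE]
      m38 <- svMatrix(g38)[, pc, drop = FALSE]
      sel <- (!is.na(m18) & m18 >= threshold_db) |
             (!is.na(m38) & m38 >= threshold_db)
      if (!any(sel)) next
      bins <- which(rowSums(sel) > 0)
      span <- c(min(rd$depth_top_m[bins]), max(rd$depth_bottom_m[bins]))
      zi <- seq(span[1] + 0.5, span[2] - 0.5, by = 1)
      prof <- ctdProfile(s)
      env <- vapply(.PREDICTORS, function(v)
        mean(.interpProfile(prof$depth_m, prof[[v]], zi)), numeric(1))
      rec <- data.frame(station_id = s@station_id, diel = ph,
                        sv18 = .meanDb(m18[sel & !is.na(m18) & m18 >= threshold_db]),
                        sv38 = .meanDb(m38[sel & !is.na(m38) & m38 >= threshold_db]),
                        t(env), location = location[si],
                        lat = s@lat, lon = s@lon,
                        depth_top_m = span[1], depth_bottom_m = span[2],
                        n_columns = length(pc))
      if ("turbidity" %in% names(prof))
        rec$turbidity <- mean(.interpProfile(prof$depth_m, prof$turbidity, zi))
      records[[length(records) + 1]] <- rec
    }
  }
  if (!length(records))
    stop("no CTD station matched any acoustic column within ", radius_nmi,
         " nmi (nearest distances: ",
         paste(round(sort(nearest)[seq_len(min(5, length(nearest)))], 2),
               collapse = ", "), " nmi)")
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Screen predictor collinearity
#'
#' Pairwise Pearson correlations among the environmental predictors, with
#' pairs at `|r| >= r_flag` flagged. The screen is advisory: the exclusion
#' list (by default turbidity, an optical proxy redundant with
#' chlorophyll-a) says which variables stay out of the models; strongly
#' correlated pairs of retained variables (e.g. temperature and oxygen) are
#' reported, not dropped.
#'
#' @param records matched records from [matchAcousticToCtd()].
#' @param r_flag flagging threshold on `|r|`.
#' @param exclude predictors excluded from modelling.
#' @return list with `correlations` (matrix), `flags` (data.frame var1,
#'   var2, r) and `excluded`.
#' @export
screenCollinearity <- function(records, r_flag = 0.8, exclude = "turbidity") {
  vars <- intersect(c(.PREDICTORS, "turbidity"), names(records))
  if (nrow(records) < 3) stop("need at least 3 records")
  m <- as.matrix(records[vars])
  const <- apply(m, 2, stats::sd) == 0
  if (any(const))
    warning("constant predictor(s), correlation undefined: ",
            paste(vars[const], collapse = ", "))
  cm <- suppressWarnings(stats::cor(m))
  flags <- which(abs(cm) >= r_flag & upper.tri(cm), arr.ind = TRUE)
  list(correlations = cm,
       flags = data.frame(var1 = rownames(cm)[flags[, 1]],
                          var2 = colnames(cm)[flags[, 2]],
                          r = cm[flags]),
       excluded = intersect(exclude, vars))
}

# Model term sets: at 18 kHz PAR enters as a smooth, at 38 kHz linearly.
.gamTerms <- function(response) {
  smooth <- c("chlorophyll_a", "oxygen", if (response == "sv18") "par")
  linear <- c("temperature", "salinity", if (response == "sv38") "par")
  list(smooth = smooth, linear = linear)
}

#' Fit the environmental driver GAM
#'
#' Models mean Sv (dB) against standardized environmental predictors with
#' identity link and Gaussian errors. The 18 kHz model is
#' `sv18 ~ Temp + s(Chla) + s(O2) + Sal + s(PAR) + Location`; at 38 kHz PAR
#' enters linearly. Smooths are penalized cubic regression splines (basis
#' dimension `k_basis`) with smoothness chosen by generalized cross
#' validation, via `mgcv::gam`. Predictors are z-scored before fitting
#' (response left in dB); the applied means/sds are recorded in the result
#' so fitted curves can be mapped back to physical units. Candidate models
#' (e.g. nested term sets via `drop_terms`) are compared by AIC.
#'
#' @param records matched records from [matchAcousticToCtd()] (or any
#'   data.frame with the response, the five predictors and `location`).
#' @param response `"sv18"` or `"sv38"`.
#' @param k_basis smooth basis dimension.
#' @param standardize z-score the predictors (default) or use them as given.
#' @param drop_terms predictors to omit (nested-model comparisons).
#' @param fixed_smooths fit the smooths as unpenalized regression splines
#'   (`fx = TRUE`). With penalization each model chooses its own smoothing,
#'   so deviance explained is only guaranteed monotone across nested term
#'   sets under a fixed smoothing setup; use this for such comparisons.
#' @return a [GAMResult].
#' @export
fitGam <- function(records, response = c("sv18", "sv38"), k_basis = 10,
                   standardize = TRUE, drop_terms = character(),
                   fixed_smooths = FALSE) {
  response <- match.arg(response)
  records <- as.data.frame(records)
  stopifnot(response %in% names(records))
  terms <- .gamTerms(response)
  terms$smooth <- setdiff(terms$smooth, drop_terms)
  terms$linear <- setdiff(terms$linear, drop_terms)
  use_loc <- "location" %in% names(records) && !"location" %in% drop_terms &&
    length(unique(records$location)) > 1
  nterm <- length(terms$smooth) + length(terms$linear) + use_loc
  if (nrow(records) < 10 * nterm)
    warning(sprintf("only %d records for %d terms (< 10 per term)",
                    nrow(records), nterm))
  preds <- c(terms$smooth, terms$linear)
  const <- preds[vapply(preds, function(v) stats::sd(records[[v]]) == 0,
                        logical(1))]
  if (length(const))
    stop("rank deficiency: constant predictor(s) ",
         paste(const, collapse = ", "))
  std <- list()
  if (standardize) {
    for (v in preds) {
      std[[v]] <- c(mean = mean(records[[v]]), sd = stats::sd(records[[v]]))
      records[[v]] <- (records[[v]] - std[[v]]["mean"]) / std[[v]]["sd"]
    }
  }
  if (use_loc) records$location <- factor(records$location)
  rhs <- c(sprintf("s(%s, bs = 'cr', k = %d%s)", terms$smooth, k_basis,
                   if (fixed_smooths) ", fx = TRUE" else ""),
           terms$linear, if (use_loc) "location")
  if (!length(rhs)) rhs <- "1"
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(form, data = records, family = stats::gaussian(),
                   method = "GCV.Cp")
  sm <- summary(fit)
  pt <- sm$p.table
  pt <- pt[rownames(pt) != "(Intercept)", , drop = FALSE]
  term_df <- rbind(
    if (nrow(pt)) data.frame(term = rownames(pt), type = "linear",
                             estimate = pt[, "Estimate"], edf = NA_real_,
                             p_value = pt[, "Pr(>|t|)"]),
    if (!is.null(sm$s.table) && nrow(sm$s.table))
      data.frame(term = rownames(sm$s.table), type = "smooth",
                 estimate = NA_real_, edf = sm$s.table[, "edf"],
                 p_value = sm$s.table[, "p-value"]))
  if (is.null(term_df))
    term_df <- data.frame(term = character(0), type = character(0),
                          estimate = numeric(0), edf = numeric(0),
                          p_value = numeric(0))
  rownames(term_df) <- NULL
  dev_expl <- 100 * sm$dev.expl
  if (!is.finite(dev_expl)) dev_expl <- 0   # degenerate zero-variance response
  new("GAMResult", response = response, terms = term_df,
      deviance_explained = dev_expl, aic = stats::AIC(fit),
      fitted = as.numeric(stats::fitted(fit)),
      residuals = as.numeric(stats::residuals(fit)),
      standardization = std, model = fit)
}

#' Residual diagnostics for a fitted driver model
#'
#' Shapiro-Wilk normality of the residuals and a Breusch-Pagan-type
#' heteroscedasticity test of the residuals against the fitted values, plus
#' a residual-vs-fitted summary. `pass` flags use `alpha` (a failed test
#' means the corresponding model assumption is questionable).
#'
#' @param result a [GAMResult].
#' @param alpha significance level for the pass/warn flags.
#' @return list with `normality`, `heteroscedasticity` (statistic, p_value,
#'   pass) and `residual_vs_fitted` (correlation and residual spread).
#' @export
gamDiagnostics <- function(result, alpha = 0.05) {
  r <- result@residuals
  f <- result@fitted
  if (length(r) < 3) {
    warning("too few residuals for diagnostics")
    return(list(normality = NULL, heteroscedasticity = NULL,
                residual_vs_fitted = NULL))
  }
  if (all(abs(r) < 1e-12)) {
    warning("residuals are numerically zero: degenerate fit, tests skipped")
    return(list(normality = NULL, heteroscedasticity = NULL,
                residual_vs_fitted = list(cor = NA_real_, sd = 0)))
  }
  swn <- stats::shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
  bp <- lmtest::bptest(r ~ f)
  list(normality = list(statistic = unname(swn$statistic),
                        p_value = swn$p.value, pass = swn$p.value > alpha),
       heteroscedasticity = list(statistic = unname(bp$statistic),
                                 p_value = bp$p.value,
                                 pass = bp$p.value > alpha),
       residual_vs_fitted = list(cor = stats::cor(f, r), sd = stats::sd(r)))
}
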