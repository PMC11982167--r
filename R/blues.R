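#' Fit one trial and extract line BLUEs
#'
#' Fits, for a single environment and element, the mixed model
#' `value = mu + line (fixed) + row + col + rep (random) + e` by REML and
#' returns the generalized-least-squares estimates of the line values
#' (best linear unbiased estimates) with their standard errors. Row, column
#' and replicate effects are independent identically distributed random
#' effects; this is a deliberate simplification of a full spatial
#' (e.g. AR1xAR1) adjustment and is documented as such.
#'
#' Random terms with fewer than two levels are dropped; if the fit is
#' singular or fails, random terms are dropped one at a time (rep, then col,
#' then row) until an ordinary least-squares fit remains, and the dropped
#' terms are recorded in the fit.
#'
#' @param plots a `plot_table` data.frame restricted to one `env` and one
#'   `element` (columns `row`, `col`, `rep`, `line_id`, `value`).
#' @return list with elements `fit` (env, element, var_row, var_col,
#'   var_rep, var_resid, loglik_reml, converged, dropped_terms) and `blues`
#'   (data.frame env, element, line_id, blue, se).
#' @export
fit_trial <- function(plots) {
  stopifnot(all(c("row", "col", "rep", "line_id", "value") %in% names(plots)))
  env <- if ("env" %in% names(plots)) as.character(plots$env[1]) else NA_character_
  element <- if ("element" %in% names(plots)) as.character(plots$element[1]) else NA_character_
  df <- data.frame(value = plots$value,
                   line = factor(plots$line_id),
                   row = factor(plots$row),
                   col = factor(plots$col),
                   rep = factor(plots$rep))
  if (nlevels(df$line) < 2) stop("need at least 2 lines")

  terms_all <- c("row", "col", "rep")
  usable <- terms_all[vapply(terms_all, function(t) nlevels(df[[t]]) >= 2, TRUE)]
  ## a random factor with one observation per level is confounded with the
  ## residual once line effects are fixed; drop it up front
  usable <- usable[vapply(usable, function(t)
    nlevels(df[[t]]) < nrow(df), TRUE)]
  dropped <- setdiff(terms_all, usable)

  vc <- c(row = 0, col = 0, rep = 0)
  fit_obj <- NULL
  converged <- TRUE
  while (TRUE) {
    if (length(usable) == 0L) {
      fit_obj <- stats::lm(value ~ 0 + line, data = df)
      break
    }
    form <- stats::as.formula(paste(
      "value ~ 0 + line +",
      paste(sprintf("(1 | %s)", usable), collapse = " + ")))
    fit_try <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form, data = df, REML = TRUE,
                   control = lme4::lmerControl(
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e) e)
    if (!inherits(fit_try, "error")) { fit_obj <- fit_try; break }
    ## drop the last usable term and retry
    dropped <- c(dropped, usable[length(usable)])
    usable <- usable[-length(usable)]
    converged <- FALSE
  }

  if (inherits(fit_obj, "merMod")) {
    vcs <- lme4::VarCorr(fit_obj)
    for (t in usable) if (!is.null(vcs[[t]])) vc[t] <- as.numeric(vcs[[t]])
    var_resid <- stats::sigma(fit_obj)^2
    loglik <- as.numeric(stats::logLik(fit_obj))
    b <- lme4::fixef(fit_obj)
    se <- sqrt(diag(as.matrix(stats::vcov(fit_obj))))
  } else {
    var_resid <- stats::sigma(fit_obj)^2
    loglik <- as.numeric(stats::logLik(fit_obj))
    b <- stats::coef(fit_obj)
    se <- sqrt(diag(stats::vcov(fit_obj)))
    se[!is.finite(se)] <- NA_real_
  }
  line_names <- sub("^line", "", names(b))
  blues <- data.frame(env = env, element = element, line_id = line_names,
                      blue = as.numeric(b), se = as.numeric(se),
                      stringsAsFactors = FALSE)
  fit <- list(env = env, element = element,
              var_row = vc[["row"]], var_col = vc[["col"]],
              var_rep = vc[["rep"]], var_resid = var_resid,
              loglik_reml = loglik, converged = converged,
              dropped_terms = dropped)
  list(fit = fit, blues = blues)
}

#' BLUEs for every environment-by-element combination
#'
#' Applies [fit_trial()] to each `env` x `element` cell present in the plot
#' table; cells with no data are skipped with a message.
#'
#' @param plots a `plot_table` data.frame.
#' @param verbose print progress messages.
#' @return list with `blues` (one data.frame, the GWAS phenotypes) and
#'   `fits` (data.frame of per-trial variance components).
#' @export
blues_all <- function(plots, verbose = FALSE) {
  combos <- unique(plots[, c("env", "element")])
  blues <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sub <- plots[plots$env == combos$env[i] & plots$element == combos$element[i], ]
    if (nrow(sub) == 0L) next
    if (verbose) message("fitting ", combos$env[i], " / ", combos$element[i])
    res <- fit_trial(sub)
    blues[[i]] <- res$blues
    f <- res$fit
    fits[[i]] <- data.frame(env = f$env, element = f$element,
                            var_row = f$var_row, var_col = f$var_col,
                            var_rep = f$var_rep, var_resid = f$var_resid,
                            loglik_reml = f$loglik_reml,
                            converged = f$converged,
                            dropped_terms = paste(f$dropped_terms, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  list(blues = do.call(rbind, blues[!vapply(blues, is.null, TRUE)]),
       fits = do.call(rbind, fits[!vapply(fits, is.null, TRUE)]))
}

#' Reshape a BLUE table into a lines-by-analysis matrix
#'
#' @param blues the `blues` data.frame from [blues_all()].
#' @param sep separator between element and environment in column labels.
#' @return numeric matrix, lines in rows, one column per `element<sep>env`
#'   analysis, `NA` where a line was not grown in an environment.
#' @export
blues_matrix <- function(blues, sep = ":") {
  lab <- paste(blues$element, blues$env, sep = sep)
  lines <- sort(unique(blues$line_id))
  cols <- unique(lab)
  m <- matrix(NA_real_, length(lines), length(cols),
              dimnames = list(lines, cols))
  m[cbind(match(blues$line_id, lines), match(lab, cols))] <- blues$blue
  m
}
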