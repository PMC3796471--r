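#' Transform excess-attenuation values towards normality
#'
#' Excess attenuation in dB can be negative, so the default is a shifted log:
#' \code{log(v - min(v) + 1)}. Alternatives: \code{"identity"} (no
#' transform) and \code{"linear_log"} (the natural log of the linear pressure
#' ratio, \code{v * ln(10)/20} — an exact rescaling of the dB values). The
#' method and shift are recorded as attributes so the transform round-trips.
#'
#' @param values numeric dB values (finite).
#' @param method one of \code{"shifted_log"}, \code{"identity"},
#'   \code{"linear_log"}.
#' @return transformed numeric with attributes \code{method} and
#'   \code{shift}.
#' @export
transform_response <- function(values,
                               method = c("shifted_log", "identity",
                                          "linear_log")) {
  method <- match.arg(method)
  if (any(!is.finite(values))) stop("non-finite response values")
  out <- switch(method,
    shifted_log = {
      shift <- 1 - min(values)
      structure(log(values + shift), shift = shift)
    },
    identity = structure(values, shift = 0),
    linear_log = structure(values * log(10) / 20, shift = 0))
  attr(out, "method") <- method
  out
}

#' Invert \code{\link{transform_response}}
#' @param transformed output of \code{\link{transform_response}}.
#' @return the original dB values.
#' @export
inv_transform_response <- function(transformed) {
  method <- attr(transformed, "method")
  shift <- attr(transformed, "shift")
  v <- switch(method,
    shifted_log = exp(as.numeric(transformed)) - shift,
    identity = as.numeric(transformed),
    linear_log = as.numeric(transformed) * 20 / log(10))
  v
}

# orthonormal contrast basis (k x (k-1)) for a k-level factor
ortho_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Sphericity diagnostics for one within-effect subspace.
# Zc: group-centered subject scores on the effect contrasts (N x p);
# n_err: error degrees of freedom (N - number of between groups).
sphericity_stats <- function(Zc, n_err) {
  p <- ncol(Zc)
  if (p == 1L)
    return(list(w = 1, p_mauchly = 1, eps_gg = 1, eps_hf = 1, df = p))
  E <- crossprod(Zc)
  tr <- sum(diag(E))
  eps_gg <- tr^2 / (p * sum(E^2))
  eps_hf <- ((n_err + 1) * p * eps_gg - 2) / (p * (n_err - p * eps_gg))
  eps_hf <- min(1, eps_hf)
  detE <- det(E / n_err)
  if (!is.finite(detE) || detE <= 0 || n_err <= p) {
    w <- NA_real_; p_m <- NA_real_
  } else {
    w <- detE / (tr / n_err / p)^p
    chisq <- -(n_err - (2 * p^2 + p + 2) / (6 * p)) * log(w)
    p_m <- stats::pchisq(chisq, p * (p + 1) / 2 - 1, lower.tail = FALSE)
  }
  list(w = w, p_mauchly = p_m, eps_gg = max(eps_gg, 1 / p),
       eps_hf = max(eps_hf, 1 / p), df = p)
}

#' Mauchly's test of sphericity for one within-subject factor
#'
#' The response is averaged per subject and factor level (over any other
#' columns), subject-level scores on orthonormal level contrasts are formed,
#' and Mauchly's W with its chi-square approximation is computed. A factor
#' with two levels is trivially spherical and returns W = 1, p = 1, flagged.
#'
#' @param data long-format data.frame.
#' @param response response column name.
#' @param subject subject-identifier column name.
#' @param within within-factor column name (>= 2 levels).
#' @param between optional between-subjects column name; its groups are used
#'   for centering.
#' @return list: \code{w}, \code{p}, \code{n_subjects}, \code{trivial}.
#' @export
mauchly_test <- function(data, response, subject, within, between = NULL) {
  f <- factor(data[[within]])
  s <- factor(data[[subject]])
  k <- nlevels(f)
  if (k < 2L) stop("within factor needs at least 2 levels")
  agg <- stats::aggregate(data[[response]],
                          by = list(s = s, f = f), FUN = mean)
  Y <- matrix(NA_real_, nlevels(s), k,
              dimnames = list(levels(s), levels(f)))
  Y[cbind(as.integer(agg$s), as.integer(agg$f))] <- agg$x
  if (anyNA(Y)) stop("incomplete subject x level crossing")
  if (k == 2L)
    return(list(w = 1, p = 1, n_subjects = nrow(Y), trivial = TRUE))
  Z <- Y %*% ortho_contrasts(k)
  if (!is.null(between)) {
    grp <- data[[between]][match(rownames(Y), as.character(s))]
    g <- nlevels(factor(grp))
    Zc <- Z - apply(Z, 2, stats::ave, factor(grp))
  } else {
    g <- 1L
    Zc <- scale(Z, scale = FALSE)
  }
  st <- sphericity_stats(Zc, nrow(Y) - g)
  list(w = st$w, p = st$p_mauchly, n_subjects = nrow(Y), trivial = FALSE)
}

#' Repeated-measures ANOVA with sphericity diagnostics
#'
#' Univariate mixed ANOVA for a balanced, completely crossed design with one
#' optional between-subjects factor and one or more within-subjects factors.
#' Sums of squares and F tests come from \code{stats::aov} with subject error
#' strata (equivalent to Type-III partitioning in a balanced design). For
#' every within-subject effect the Greenhouse-Geisser and Huynh-Feldt
#' epsilons (the latter truncated at 1) and Mauchly's test are computed from
#' the subject scores on the effect's orthonormal contrasts, and a
#' Huynh-Feldt corrected p-value is obtained from the epsilon-scaled F
#' distribution. The reported p-value follows \code{correction}:
#' \code{"auto"} (default) applies the correction only where Mauchly's test
#' rejects sphericity at 0.05 (or where W is inestimable), \code{"always"}
#' and \code{"never"} force one behaviour.
#'
#' @param data long-format data.frame, one row per subject x within-cell.
#' @param response response column name (e.g. transformed excess
#'   attenuation).
#' @param subject subject-identifier column name.
#' @param within character vector of within-factor column names.
#' @param between optional between-subjects factor column name.
#' @param correction \code{"auto"}, \code{"always"} or \code{"never"}.
#' @param epsilon \code{"hf"} (default) or \code{"gg"} for the corrected
#'   p-values.
#' @return object of class \code{"rm_anova"}: list with \code{table} (one row
#'   per effect: effect, df_num, df_den, F, p, mauchly_w, mauchly_p,
#'   epsilon_gg, epsilon_hf, p_corrected, p_reported, corrected),
#'   \code{shapiro_p} (Shapiro-Wilk on within-cell residuals), and the design
#'   description.
#' @export
rm_anova <- function(data, response, subject, within, between = NULL,
                     correction = c("auto", "always", "never"),
                     epsilon = c("hf", "gg")) {
  correction <- match.arg(correction)
  epsilon <- match.arg(epsilon)
  stopifnot(length(within) >= 1L,
            all(c(response, subject, within, between) %in% names(data)))
  d <- data
  d[[subject]] <- droplevels(factor(d[[subject]]))
  for (w in within) d[[w]] <- droplevels(factor(d[[w]]))
  if (!is.null(between)) d[[between]] <- droplevels(factor(d[[between]]))

  # balance checks: complete within crossing per subject, one row per cell
  cell <- interaction(d[within], drop = FALSE)
  tab <- table(d[[subject]], cell)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop("unbalanced design: subject ", rownames(tab)[bad[1]],
         " has ", tab[bad[1], bad[2]], " row(s) in cell ",
         colnames(tab)[bad[2]])
  }
  if (!is.null(between)) {
    map <- table(d[[subject]], d[[between]])
    if (any(rowSums(map > 0) != 1L))
      stop("each subject must belong to exactly one between-subjects group")
    if (any(colSums(map > 0) < 2L))
      stop("every between-subjects group needs at least 2 subjects")
  }

  fixed <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(",
                paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(response, "~", fixed, "+", err))
  fit <- stats::aov(form, data = d)
  smry <- summary(fit)

  # subject x cell matrix, cells ordered with the first within factor fastest
  lv <- lapply(d[within], levels)
  cells <- do.call(expand.grid,
                   c(lv, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE))
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  row_key <- do.call(paste, c(lapply(d[within], as.character), sep = "\r"))
  subj <- d[[subject]]
  Y <- matrix(NA_real_, nlevels(subj), length(cell_key),
              dimnames = list(levels(subj), cell_key))
  Y[cbind(as.integer(subj), match(row_key, cell_key))] <- d[[response]]
  if (!is.null(between)) {
    grp <- factor(d[[between]][match(levels(subj), as.character(subj))])
    g <- nlevels(grp)
  } else {
    grp <- factor(rep(1, nrow(Y)))
    g <- 1L
  }
  n_err <- nrow(Y) - g

  # sphericity stats per within-effect subspace
  subsets <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  sph <- list()
  for (S in subsets) {
    mats <- lapply(within, function(w) {
      k <- length(lv[[w]])
      if (w %in% S) ortho_contrasts(k) else matrix(1 / sqrt(k), k, 1)
    })
    M <- Reduce(`%x%`, rev(mats))
    Z <- Y %*% M
    Zc <- Z - apply(Z, 2, stats::ave, grp)
    sph[[paste(sort(S), collapse = ":")]] <- sphericity_stats(Zc, n_err)
  }

  # collect effects from the aov strata
  rows <- list()
  for (stratum in smry) {
    st <- stratum[[1]]
    rn <- trimws(rownames(st))
    res_i <- which(rn == "Residuals")
    if (length(res_i) == 0L) next
    df_den <- st$Df[res_i]
    for (i in setdiff(seq_along(rn), res_i)) {
      eff <- rn[i]
      parts <- strsplit(eff, ":", fixed = TRUE)[[1]]
      wpart <- sort(intersect(parts, within))
      key <- paste(wpart, collapse = ":")
      s <- if (length(wpart)) sph[[key]] else NULL
      Fv <- st$`F value`[i]; df1 <- st$Df[i]
      eps_use <- if (is.null(s)) NA_real_
                 else if (epsilon == "hf") s$eps_hf else s$eps_gg
      p_unc <- st$`Pr(>F)`[i]
      p_cor <- if (is.null(s)) p_unc
               else stats::pf(Fv, df1 * eps_use, df_den * eps_use,
                              lower.tail = FALSE)
      mau_p <- if (is.null(s)) NA_real_ else s$p_mauchly
      needs <- !is.null(s) && s$df > 1L &&
        (is.na(mau_p) || mau_p < 0.05)
      corrected <- switch(correction,
                          auto = needs,
                          always = !is.null(s) && s$df > 1L,
                          never = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = eff, df_num = df1, df_den = df_den, F = Fv, p = p_unc,
        mauchly_w = if (is.null(s)) NA_real_ else s$w,
        mauchly_p = mau_p,
        epsilon_gg = if (is.null(s)) NA_real_ else s$eps_gg,
        epsilon_hf = if (is.null(s)) NA_real_ else s$eps_hf,
        p_corrected = p_cor,
        p_reported = if (corrected) p_cor else p_unc,
        corrected = corrected, stringsAsFactors = FALSE)
    }
  }
  tab_out <- do.call(rbind, rows)
  rownames(tab_out) <- NULL

  # Shapiro-Wilk on within-cell residuals (cell means and subject effects
  # removed)
  full_cell <- if (is.null(between)) cell
               else interaction(d[[between]], cell, drop = TRUE)
  r <- d[[response]] - stats::ave(d[[response]], full_cell) -
    stats::ave(d[[response]], d[[subject]]) +
    stats::ave(d[[response]], grp[as.integer(subj)])
  rs <- if (length(r) > 5000) sample(r, 5000) else r
  shapiro_p <- tryCatch(stats::shapiro.test(rs)$p.value,
                        error = function(e) NA_real_)

  structure(list(table = tab_out, shapiro_p = shapiro_p,
                 design = list(subject = subject, between = between,
                               within = within, n_subjects = nrow(Y),
                               n_groups = g, correction = correction,
                               epsilon = epsilon)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$design$n_subjects, " subjects, ",
      "between: ", if (is.null(x$design$between)) "none"
      else x$design$between,
      "; within: ", paste(x$design$within, collapse = ", "), ")\n", sep = "")
  tab <- x$table
  tab$F <- round(tab$F, 2)
  for (cc in c("p", "mauchly_p", "epsilon_hf", "p_reported"))
    tab[[cc]] <- signif(tab[[cc]], 3)
  print(tab[, c("effect", "F", "df_num", "df_den", "p", "epsilon_hf",
                "p_reported", "corrected")], row.names = FALSE)
  cat(sprintf("Shapiro-Wilk residual normality: p = %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons for a repeated factor
#'
#' The response is averaged per subject and factor level, every level pair is
#' compared with a paired t-test, and p-values are multiplied by the number
#' of pairs (capped at 1).
#'
#' @param data long-format data.frame.
#' @param response response column name.
#' @param subject subject column name.
#' @param factor_name column name of the factor to compare (>= 2 levels).
#' @return data.frame: level_1, level_2, mean_diff, t, df, p_raw,
#'   p_bonferroni.
#' @export
bonferroni_pairwise <- function(data, response, subject, factor_name) {
  f <- factor(data[[factor_name]])
  if (nlevels(f) < 2L) stop("factor needs at least 2 levels")
  s <- factor(data[[subject]])
  agg <- stats::aggregate(data[[response]], list(s = s, f = f), mean)
  wide <- matrix(NA_real_, nlevels(s), nlevels(f),
                 dimnames = list(levels(s), levels(f)))
  wide[cbind(as.integer(agg$s), as.integer(agg$f))] <- agg$x
  prs <- utils::combn(levels(f), 2, simplify = FALSE)
  m <- length(prs)
  rows <- lapply(prs, function(pr) {
    tt <- stats::t.test(wide[, pr[1]], wide[, pr[2]], paired = TRUE)
    data.frame(level_1 = pr[1], level_2 = pr[2],
               mean_diff = unname(tt$estimate), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_bonferroni = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
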