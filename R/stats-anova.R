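# Two-way repeated-measures ANOVA (ball size x feedback cell), with
# Mauchly's sphericity test and Greenhouse-Geisser correction, written as an
# explicit within-subject sums-of-squares decomposition.

# Orthonormal contrast matrix (k x (k-1)) for a k-level within factor.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Mauchly's W, its chi-square p-value and the Greenhouse-Geisser epsilon for
# an n x k matrix of subject-by-level responses.
mauchly_stats <- function(Y) {
  k <- ncol(Y)
  n <- nrow(Y)
  d <- k - 1L
  if (d < 1L) rlang::abort("the factor needs at least 2 levels.")
  if (d == 1L) {
    return(list(W = 1, p = NA_real_, epsilon = 1, df = 0L))
  }
  M <- orthonormal_contrasts(k)
  S <- stats::cov(Y %*% M)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  W <- det(S) / (sum(diag(S)) / d)^d
  if (!is.finite(W) || W <= 0) {
    return(list(W = W, p = NA_real_, epsilon = eps, df = d * (d + 1L) / 2L - 1L))
  }
  f <- (2 * d^2 + d + 2) / (6 * d * (n - 1))
  X2 <- -(n - 1) * (1 - f) * log(W)
  df <- d * (d + 1L) / 2L - 1L
  list(W = W, p = stats::pchisq(X2, df, lower.tail = FALSE),
       epsilon = eps, df = df)
}

#' Mauchly's sphericity test for a within-subject factor
#'
#' Tests sphericity of the covariance of orthonormal contrasts of the
#' factor's levels (averaging over any other within factor), and returns the
#' Greenhouse-Geisser epsilon alongside. A 2-level factor is trivially
#' spherical (`W = 1`, epsilon `= 1`).
#'
#' @param data Long-format tibble.
#' @param factor Name of the within factor column.
#' @param subject Name of the subject id column.
#' @param response Name of the response column.
#' @return A one-row tibble: `factor`, `W`, `p`, `epsilon_gg`, `df`.
#' @export
mauchly_rm <- function(data, factor, subject = "participant",
                       response = "value") {
  Y <- subject_level_matrix(data, factor, subject, response)
  ms <- mauchly_stats(Y)
  tibble::tibble(factor = factor, W = ms$W, p = ms$p,
                 epsilon_gg = ms$epsilon, df = ms$df)
}

# n x k matrix of subject means per level of `factor`.
subject_level_matrix <- function(data, factor, subject, response) {
  agg <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(subject, factor)))) |>
    dplyr::summarise(.m = mean(.data[[response]]), .groups = "drop")
  counts <- table(agg[[subject]])
  if (length(unique(counts)) != 1L) {
    rlang::abort("design is unbalanced: subjects differ in observed levels.")
  }
  wide <- tidyr::pivot_wider(agg, names_from = dplyr::all_of(factor),
                             values_from = ".m")
  Y <- as.matrix(wide[-1])
  if (anyNA(Y)) rlang::abort("design has missing (subject, level) cells.")
  Y
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject decomposition for a complete balanced two-factor design
#' (both factors within subjects): main effects and their interaction, each
#' tested against its own subject-by-effect error term. Mauchly's test is
#' computed for every effect with more than one numerator degree of freedom;
#' under the `"auto"` policy the Greenhouse-Geisser correction is applied to
#' an effect when its sphericity test rejects at the 0.05 level.
#'
#' @param data Long-format tibble with one value per subject and cell.
#' @param factor_a,factor_b Names of the two within-factor columns
#'   (defaults `"ball_mode"` and `"cell"`).
#' @param subject Name of the subject id column.
#' @param response Name of the response column.
#' @param sphericity `"auto"` (GG when Mauchly rejects), `"always"` (GG on
#'   every multi-df effect) or `"none"`.
#'
#' @return An object of class `rm_anova`: a list with `table` (one row per
#'   effect: `effect`, `df1`, `df2`, `F`, `p`, `epsilon`, `corrected`),
#'   `mauchly`, `ss` (all sums of squares) and design sizes. Use
#'   [tidy.rm_anova()] / [glance.rm_anova()] for tibble views.
#' @export
rm_anova2 <- function(data, factor_a = "ball_mode", factor_b = "cell",
                      subject = "participant", response = "value",
                      sphericity = c("auto", "always", "none")) {
  sphericity <- match.arg(sphericity)
  need <- c(factor_a, factor_b, subject, response)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rlang::abort(paste0("data is missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  subj <- as.character(data[[subject]])
  fa <- as.character(data[[factor_a]])
  fb <- as.character(data[[factor_b]])
  y <- data[[response]]
  s_lev <- unique(subj); a_lev <- unique(fa); b_lev <- unique(fb)
  n <- length(s_lev); a <- length(a_lev); b <- length(b_lev)
  if (n < 2L) rlang::abort("need at least 2 subjects.")
  counts <- table(subj, fa, fb)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)
    rlang::abort(paste0(
      "design must have exactly one value per (subject, ", factor_a, ", ",
      factor_b, ") cell; first problem: subject ",
      dimnames(counts)[[1]][bad[1, 1]], ", ",
      dimnames(counts)[[2]][bad[1, 2]], " x ",
      dimnames(counts)[[3]][bad[1, 3]], "."))
  }
  Y <- array(NA_real_, c(n, a, b))
  Y[cbind(match(subj, s_lev), match(fa, a_lev), match(fb, b_lev))] <- y

  gm <- mean(Y)
  m_s <- apply(Y, 1, mean)
  m_a <- apply(Y, 2, mean)
  m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean)
  m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss <- list(
    subject = a * b * sum((m_s - gm)^2),
    A  = n * b * sum((m_a - gm)^2),
    B  = n * a * sum((m_b - gm)^2),
    AB = n * sum((m_ab - outer(m_a, rep(1, b)) -
                    outer(rep(1, a), m_b) + gm)^2),
    As = b * sum((m_sa - outer(m_s, rep(1, a)) -
                    outer(rep(1, n), m_a) + gm)^2),
    Bs = a * sum((m_sb - outer(m_s, rep(1, b)) -
                    outer(rep(1, n), m_b) + gm)^2),
    total = sum((Y - gm)^2)
  )
  ss$ABs <- ss$total - ss$subject - ss$A - ss$B - ss$AB - ss$As - ss$Bs

  df <- list(A = a - 1L, B = b - 1L, AB = (a - 1L) * (b - 1L),
             As = (a - 1L) * (n - 1L), Bs = (b - 1L) * (n - 1L),
             ABs = (a - 1L) * (b - 1L) * (n - 1L))

  cell_mat <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)  # n x (b*a), A slow
  # effect-specific sphericity inputs
  mstats <- list(
    A = mauchly_stats(m_sa),
    B = mauchly_stats(m_sb),
    AB = {
      Ma <- orthonormal_contrasts(a)
      Mb <- orthonormal_contrasts(b)
      M <- kronecker(Ma, Mb)  # (a*b) x (a-1)(b-1), matching cell_mat layout
      d <- (a - 1L) * (b - 1L)
      if (d == 1L) list(W = 1, p = NA_real_, epsilon = 1, df = 0L)
      else {
        S <- stats::cov(cell_mat %*% M)
        eps <- sum(diag(S))^2 / (d * sum(S^2))
        W <- det(S) / (sum(diag(S)) / d)^d
        if (!is.finite(W) || W <= 0) {
          list(W = W, p = NA_real_, epsilon = eps, df = d * (d + 1L) / 2L - 1L)
        } else {
          f <- (2 * d^2 + d + 2) / (6 * d * (n - 1))
          X2 <- -(n - 1) * (1 - f) * log(W)
          list(W = W,
               p = stats::pchisq(X2, d * (d + 1L) / 2L - 1L,
                                 lower.tail = FALSE),
               epsilon = eps, df = d * (d + 1L) / 2L - 1L)
        }
      }
    }
  )

  eff_names <- c(A = factor_a, B = factor_b,
                 AB = paste0(factor_a, ":", factor_b))
  err_of <- c(A = "As", B = "Bs", AB = "ABs")
  rows <- purrr::map(c("A", "B", "AB"), function(e) {
    ms_eff <- ss[[e]] / df[[e]]
    ms_err <- ss[[err_of[[e]]]] / df[[err_of[[e]]]]
    Fv <- if (ms_err <= 0) NA_real_ else ms_eff / ms_err
    msp <- mstats[[e]]
    correct <- switch(sphericity,
      none = FALSE,
      always = df[[e]] > 1L,
      auto = df[[e]] > 1L && is.finite(msp$p) && !is.na(msp$p) &&
        msp$p < 0.05
    )
    epsilon <- if (correct) msp$epsilon else 1
    d1 <- df[[e]] * epsilon
    d2 <- df[[err_of[[e]]]] * epsilon
    p <- if (is.na(Fv)) {
      # a zero error term with a zero effect is a degenerate null effect
      if (ss[[e]] <= 1e-12) 1 else NA_real_
    } else {
      stats::pf(Fv, d1, d2, lower.tail = FALSE)
    }
    if (is.na(Fv) && ss[[e]] <= 1e-12) Fv <- 0
    tibble::tibble(effect = eff_names[[e]], df1 = d1, df2 = d2,
                   F = Fv, p = p, epsilon = epsilon, corrected = correct)
  })
  mau <- purrr::map2(c("A", "B", "AB"), mstats, function(e, m) {
    tibble::tibble(effect = eff_names[[e]], W = m$W, p = m$p,
                   epsilon_gg = m$epsilon)
  })
  structure(list(table = dplyr::bind_rows(rows),
                 mauchly = dplyr::bind_rows(mau),
                 ss = ss, df = df,
                 n_subjects = n, levels_a = a_lev, levels_b = b_lev,
                 factors = c(factor_a, factor_b),
                 sphericity = sphericity),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (", x$factors[1], " x ",
      x$factors[2], ", n = ", x$n_subjects, ")\n", sep = "")
  tb <- x$table
  tb$sig <- significance_stars(tb$p)
  print(as.data.frame(tb), digits = 4)
  invisible(x)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Tidy an rm_anova object
#'
#' @param x An [rm_anova2()] fit.
#' @param ... Unused.
#' @return One row per effect: `effect`, `df1`, `df2`, `F`, `p`, `epsilon`,
#'   `corrected`, plus Mauchly's `W` and sphericity p-value.
#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) {
  dplyr::left_join(
    x$table,
    dplyr::rename(x$mauchly, mauchly_W = "W", mauchly_p = "p"),
    by = "effect"
  )
}

#' Glance at an rm_anova object
#'
#' @param x An [rm_anova2()] fit.
#' @param ... Unused.
#' @return A one-row tibble with design sizes and total sum of squares.
#' @exportS3Method generics::glance
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_levels_a = length(x$levels_a),
    n_levels_b = length(x$levels_b),
    ss_total = x$ss$total,
    sphericity_policy = x$sphericity
  )
}
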