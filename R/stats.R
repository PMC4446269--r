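#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. When
#' `n_a + n_b <= exact_max_n` the two-sided p-value is exact by full
#' enumeration of all `choose(n_a + n_b, n_a)` group labelings of the pooled
#' midranks: `p = P(|U - n_a n_b / 2| >= |u_obs - n_a n_b / 2|)`. For larger
#' samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max_n enumeration cutoff on `n_a + n_b` (default 12).
#' @return Object of class `rank_test`: `statistic` (U for sample `a`),
#'   `p_value`, `n` (per-group sizes), `method`, `stars`.
#' @export
mann_whitney_u <- function(a, b, exact_max_n = 12L) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b)) # midranks for ties
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_max_n) {
    combs <- utils::combn(n, na)
    u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "Mann-Whitney U, exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "Mann-Whitney U, normal approximation with tie correction"
  }
  new_rank_test(u_obs, p, c(n_a = na, n_b = nb), method)
}

#' Kruskal-Wallis rank test across groups
#'
#' Wraps [stats::kruskal.test()] (H statistic with tie correction,
#' chi-square reference with k - 1 df) and returns the package's common
#' test-result container.
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return A `rank_test` object with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  # all-identical data: kruskal.test returns NaN (0/0); H is 0 by definition
  h <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (!is.finite(h)) { h <- 0; p <- 1 }
  new_rank_test(h, p, lengths(groups), "Kruskal-Wallis rank sum test")
}

new_rank_test <- function(statistic, p_value, n, method) {
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         n = n, method = method, stars = significance_stars(p_value)),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s\n  statistic = %.6g, p = %.4g %s (n = %s)\n",
              x$method, x$statistic, x$p_value, x$stars,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @rdname mann_whitney_u
#' @param x a `rank_test` object.
#' @param ... unused.
#' @method tidy rank_test
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, stars = x$stars)
}

#' @rdname mann_whitney_u
#' @method glance rank_test
#' @export
glance.rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_total = sum(x$n), n_groups = length(x$n),
                 method = x$method, stars = x$stars)
}

#' Significance star annotation
#'
#' `p < 0.001` gives `"***"`, `p < 0.01` `"**"`, `p < 0.05` `"*"`, otherwise
#' `"ns"`; boundaries are exclusive, so `p = 0.05` is not significant.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
                    ifelse(p[ok] < 0.01, "**",
                           ifelse(p[ok] < 0.05, "*", "ns")))
  out
}
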