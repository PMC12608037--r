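#' @title Cassette-type x pathotype association statistics
#' @name association_stats
#' @description
#' The 2x2 table lays out rows = cassette type (short, long) and columns =
#' pathotype (pathogenic, non-pathogenic). The sample odds ratio is
#' (a*d)/(b*c) with the Haldane-Anscombe +0.5 correction when any cell is
#' zero. The exact test conditions on the margins: the two-sided p-value is
#' the sum of hypergeometric point probabilities not exceeding that of the
#' observed table (point-probability method, the convention of mainstream
#' statistical software), computed in log space so totals of 10,000+ are
#' exact to double precision. No phylogenetic correction for strain
#' non-independence is applied (a stated limitation).
NULL

#' Construct a 2x2 contingency table
#'
#' @param a Count short & pathogenic.
#' @param b Count short & non-pathogenic.
#' @param c Count long & pathogenic.
#' @param d Count long & non-pathogenic.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) <= 0) stop("empty table: total count must be positive")
  structure(as.list(counts), n = sum(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("short", "long"),
                              c("pathogenic", "non-pathogenic")))
  print(m)
  invisible(x)
}

#' Build the cassette-type x pathotype contingency table
#'
#' Strains with variant SHORT or LONG and a known pathotype are counted;
#' PARTIAL/NONE strains are excluded (the analysis dichotomizes short vs.
#' long), as are strains with a variant but missing pathotype (with a
#' warning). Exclusion counts are attached as attributes.
#'
#' @param variants Named character vector: strain -> variant
#'   (LONG/SHORT/PARTIAL/NONE).
#' @param pathotypes Named character vector: strain -> pathotype
#'   ("pathogenic"/"non-pathogenic").
#' @return A [contingency_table()] with attributes `excluded_variant`
#'   (PARTIAL/NONE count) and `excluded_missing` (missing-pathotype count).
#' @export
build_contingency <- function(variants, pathotypes) {
  if (length(variants) == 0) stop("empty panel: no variants supplied")
  informative <- variants %in% c("SHORT", "LONG")
  excluded_variant <- sum(!informative)
  v <- variants[informative]
  p <- pathotypes[names(v)]
  known <- !is.na(p) & p %in% c("pathogenic", "non-pathogenic")
  excluded_missing <- sum(!known)
  if (excluded_missing > 0)
    warning(excluded_missing,
            " strain(s) with a variant but no pathotype excluded")
  v <- v[known]; p <- p[known]
  if (length(v) == 0) stop("no strains with both variant and pathotype")
  tab <- contingency_table(sum(v == "SHORT" & p == "pathogenic"),
                           sum(v == "SHORT" & p == "non-pathogenic"),
                           sum(v == "LONG" & p == "pathogenic"),
                           sum(v == "LONG" & p == "non-pathogenic"))
  attr(tab, "excluded_variant") <- excluded_variant
  attr(tab, "excluded_missing") <- excluded_missing
  tab
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction adds
#' 0.5 to every cell first (flagged via the `"correction_applied"`
#' attribute). The sample OR (not the conditional MLE) is reported.
#'
#' @param table A [contingency_table()].
#' @return Positive numeric with attribute `correction_applied`.
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure((cells[1] * cells[4]) / (cells[2] * cells[3]),
            correction_applied = corrected)
}

# Vectorized two-sided mid-free exact p for observed cell(s) `a` of tables
# with first-row total r1, first-column total c1, grand total n. Log-space
# hypergeometric point probabilities; a table counts as "at least as
# extreme" when its point probability is <= observed * (1 + 1e-7)
# (relative tolerance guards floating-point ties).
.fisher_p_core <- function(a, r1, c1, n, alternative = "two.sided",
                           rel_tol = 1e-7) {
  amin <- max(0L, r1 + c1 - n)
  amax <- min(r1, c1)
  supp <- amin:amax
  lp <- lchoose(r1, supp) + lchoose(n - r1, c1 - supp) - lchoose(n, c1)
  M <- max(lp)
  pr <- exp(lp - M) # rescaled point probabilities, max = 1
  idx <- match(a, supp)
  if (anyNA(idx)) stop("observed count outside the admissible range")
  if (alternative == "two.sided") {
    thr <- lp[idx] + log1p(rel_tol)
    vapply(thr, function(t) min(1, sum(pr[lp <= t]) * exp(M)), numeric(1))
  } else if (alternative == "greater") {
    vapply(idx, function(i) min(1, sum(pr[supp >= supp[i]]) * exp(M)),
           numeric(1))
  } else {
    vapply(idx, function(i) min(1, sum(pr[supp <= supp[i]]) * exp(M)),
           numeric(1))
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Computed from first principles (no call to `stats::fisher.test`): with
#' margins fixed, the two-sided p-value sums the hypergeometric
#' probabilities of all tables whose point probability is at most that of
#' the observed table times (1 + 1e-7). Degenerate margins (a zero row or
#' column total) give p = 1 by convention, flagged via the `"degenerate"`
#' attribute.
#'
#' @param table A [contingency_table()].
#' @param alternative `"two.sided"` (default), `"greater"` (association of
#'   short with pathogenic), or `"less"`.
#' @return p-value in `[0, 1]` with attribute `degenerate`.
#' @export
fisher_exact_two_sided <- function(table,
                                   alternative = c("two.sided", "greater",
                                                   "less")) {
  stopifnot(inherits(table, "contingency_table"))
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n)
    return(structure(1.0, degenerate = TRUE))
  structure(.fisher_p_core(a, r1, c1, n, alternative),
            degenerate = FALSE)
}

#' Cassette-type x pathotype association
#'
#' Builds the 2x2 table from variant calls and metadata and reports counts,
#' sample odds ratio, exact p-value and bookkeeping in one result object.
#'
#' @param variants Named strain -> variant vector (or a
#'   [contingency_table()] directly).
#' @param pathotypes Named strain -> pathotype vector (ignored when
#'   `variants` is already a table).
#' @param alternative Sidedness, passed to [fisher_exact_two_sided()].
#' @return Object of class `association_result`: list with `table` (a, b, c,
#'   d), `odds_ratio`, `p_value`, `n`, `correction_applied`, `alternative`,
#'   `excluded_variant`, `excluded_missing`.
#' @export
associate <- function(variants, pathotypes = NULL,
                      alternative = "two.sided") {
  tab <- if (inherits(variants, "contingency_table")) variants
         else build_contingency(variants, pathotypes)
  or <- odds_ratio(tab)
  p <- fisher_exact_two_sided(tab, alternative)
  structure(list(
    table = c(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
    odds_ratio = as.numeric(or), p_value = as.numeric(p),
    n = attr(tab, "n"),
    correction_applied = isTRUE(attr(or, "correction_applied")),
    degenerate = isTRUE(attr(p, "degenerate")),
    alternative = alternative,
    excluded_variant = attr(tab, "excluded_variant") %||% 0L,
    excluded_missing = attr(tab, "excluded_missing") %||% 0L),
    class = "association_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(paste0("<association_result> n = %d, OR = %.3f%s, ",
                     "p (%s) = %.3g\n"),
              x$n, x$odds_ratio,
              if (x$correction_applied) " (Haldane-Anscombe)" else "",
              x$alternative, x$p_value))
  invisible(x)
}
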