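# Composition-proportional null, chi-squared goodness of fit, exact Fisher
# tests, and the per-phenotype enrichment scan.

#' Expected counts under the composition-proportional null
#'
#' `E_i = f_i * N`: the number of variants expected in each category if all N
#' variants were distributed over residues at random, proportionally to the
#' fraction of residues in the category. Values are kept as reals, not
#' rounded.
#'
#' @param composition a `composition_table` from [composition()], or any data
#'   frame with columns `category` and `fraction`.
#' @param N total number of variants (>= 0).
#' @return Named numeric vector of expected counts.
#' @examples
#' comp <- data.frame(category = c("helix", "sheet", "loop"),
#'                    fraction = c(0.39, 0.12, 0.49))
#' expected_counts(comp, 119)
#' @export
expected_counts <- function(composition, N) {
  if (!is.data.frame(composition) ||
      !all(c("category", "fraction") %in% names(composition))) {
    stop("composition must have columns category and fraction")
  }
  if (length(N) != 1L || is.na(N) || N < 0) stop("N must be a single number >= 0")
  f <- composition$fraction
  if (abs(sum(f) - 1) > 1e-9) stop("composition fractions must sum to 1")
  stats::setNames(f * N, composition$category)
}

#' Upper-tail probability of the chi-squared distribution
#'
#' @param x statistic value, `x >= 0`.
#' @param df degrees of freedom, integer `>= 1`.
#' @return `P(X > x)` for `X ~ chi-squared(df)`.
#' @examples
#' chi2_sf(1.202, 2)  # ~0.548
#' @export
chi2_sf <- function(x, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(x < 0)) stop("x must be >= 0")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Lower-tail quantile of the chi-squared distribution
#'
#' @param q probability in (0, 1).
#' @param df degrees of freedom, integer `>= 1`.
#' @return The value x with `P(X <= x) = q`.
#' @examples
#' chi2_quantile(0.95, 2)  # ~5.99
#' chi2_quantile(0.95, 6)  # ~12.59
#' @export
chi2_quantile <- function(q, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)")
  stats::qchisq(q, df)
}

#' Chi-squared goodness-of-fit test against given expected counts
#'
#' Computes `X^2 = sum (O_i - E_i)^2 / E_i` with `df = k - 1` and the
#' upper-tail p-value. Expected counts must all be positive; a zero expected
#' cell is an error suggesting a category merge.
#'
#' @param observed integer counts per category.
#' @param expected positive real expected counts, same length.
#' @return An object of classes `gof_test` and `htest`.
#' @examples
#' chi2_gof(c(8, 2), c(5, 5))
#' @export
chi2_gof <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length")
  }
  if (length(observed) < 2L) stop("need at least two categories")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (any(expected <= 0)) {
    stop("expected count of zero: merge that category with another")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- chi2_sf(stat, df)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df),
                 p.value = p,
                 observed = observed, expected = expected,
                 method = "Chi-squared goodness-of-fit against composition-proportional expected counts",
                 data.name = sprintf("%d categories, N = %g",
                                     length(observed), sum(observed))),
            class = c("gof_test", "htest"))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability rule: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (relative tolerance 1e-12 on the
#' comparison). A table with an empty margin is degenerate and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`:
#'   row 1 the focal group (in-category, not-in-category), row 2 the
#'   background.
#' @param alternative `"two.sided"` (default) or `"greater"` for enrichment
#'   of the focal group in the category.
#' @return The p-value.
#' @examples
#' fisher_two_sided(rbind(c(3, 1), c(1, 3)))  # 34/70
#' @export
fisher_two_sided <- function(table, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (a + b + c + d == 0) stop("at least one margin must be positive")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(1)
  }
  m <- a + b          # focal group size
  nn <- c + d         # background size
  k <- a + c          # in-category margin
  lo <- max(0, k - nn)
  hi <- min(m, k)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, nn, k)
  p_obs <- probs[match(a, xs)]
  p <- if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-12)])
  } else {
    sum(probs[xs >= a])
  }
  min(p, 1)
}

#' Format p-values in the report's display convention
#'
#' Two decimals, with values below 0.005 rendered `"<0.01"`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.005, "<0.01", sprintf("%.2f", p))
}

#' Enrichment scan: exact Fisher tests per phenotype and category
#'
#' For each cortical-malformation phenotype and each residue category, builds
#' a 2x2 table and computes the two-sided exact Fisher p-value, alongside a
#' global chi-squared goodness-of-fit of all variants (clinically labeled or
#' not) against the composition-proportional null. Variants labeled
#' `not_available` are dropped from the per-phenotype tests first.
#'
#' Table construction per `background` mode, for phenotype m and category s
#' with `x` variants of m in s out of `n_m`:
#' \describe{
#'   \item{residues}{row 2 is the residue composition: `(R_s, R_tot - R_s)`
#'     (default; the null is composition-based).}
#'   \item{expected}{row 2 is the rounded expected split of `n_m` under the
#'     null: `(round(f_s n_m), n_m - round(f_s n_m))`.}
#'   \item{other_mutations}{row 2 counts all other variants in/not in s.}
#' }
#'
#' @param table a `mutation_table` from [load_variant_table()] or
#'   [make_variant_table()].
#' @param labels named character vector mapping residue position to category.
#' @param composition a `composition_table` giving the null fractions and
#'   residue counts per category.
#' @param background one of `"residues"`, `"expected"`, `"other_mutations"`.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param alternative passed to [fisher_two_sided()].
#' @param adjust add a Benjamini-Hochberg adjusted-p column (off by default;
#'   the primary report shows raw p-values).
#' @return An object of class `enrich_scan` with elements `results` (one row
#'   per phenotype x category), `gof`, `composition`, and the options used.
#' @export
enrichment_scan <- function(table, labels, composition,
                            background = c("residues", "expected",
                                           "other_mutations"),
                            alpha = 0.05,
                            alternative = c("two.sided", "greater"),
                            adjust = FALSE) {
  background <- match.arg(background)
  alternative <- match.arg(alternative)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(is.data.frame(table),
            all(c("position", "phenotype") %in% names(table)))
  if (!all(c("category", "count", "fraction") %in% names(composition))) {
    stop("composition must have columns category, count, fraction")
  }
  cats <- composition$category
  cat_of <- unname(labels[as.character(table$position)])
  if (anyNA(cat_of)) {
    stop(sprintf("variant at unlabeled position %s",
                 table$position[which(is.na(cat_of))[1]]))
  }
  if (!all(cat_of %in% cats)) stop("variant category outside the composition")

  clinical <- table$phenotype != "not_available"
  n_dropped <- sum(!clinical)
  R <- stats::setNames(composition$count, cats)
  R_tot <- sum(R)
  f <- stats::setNames(composition$fraction, cats)

  rows <- vector("list", length(CLINICAL_PHENOTYPES) * length(cats))
  i <- 0L
  for (m in CLINICAL_PHENOTYPES) {
    in_m <- clinical & table$phenotype == m
    n_m <- sum(in_m)
    if (n_m == 0L) {
      warning(sprintf("phenotype '%s' has zero variants; its rows get p = 1", m),
              call. = FALSE)
    }
    for (s in cats) {
      x <- sum(in_m & cat_of == s)
      degenerate <- n_m == 0L
      if (degenerate) {
        p <- 1
      } else {
        row2 <- switch(background,
          residues = c(R[[s]], R_tot - R[[s]]),
          expected = {
            e <- round(f[[s]] * n_m)
            c(e, n_m - e)
          },
          other_mutations = {
            oth <- !in_m
            c(sum(oth & cat_of == s), sum(oth & cat_of != s))
          })
        tab <- rbind(c(x, n_m - x), row2)
        p <- if (sum(row2) == 0) 1 else fisher_two_sided(tab, alternative)
      }
      i <- i + 1L
      rows[[i]] <- data.frame(phenotype = m, category = s, observed = x,
                              n = n_m, p = p, degenerate = degenerate,
                              stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  if (adjust) results$p_adj <- stats::p.adjust(results$p, method = "BH")
  results$significant <- results$p < alpha

  N_all <- nrow(table)
  obs_all <- as.integer(table(factor(cat_of, levels = cats)))
  gof <- chi2_gof(obs_all, expected_counts(composition, N_all))

  structure(list(results = results, gof = gof, composition = composition,
                 background = background, alpha = alpha,
                 alternative = alternative,
                 n_total = N_all, n_clinical = sum(clinical),
                 n_dropped = n_dropped, labels = labels),
            class = "enrich_scan")
}

#' @export
print.enrich_scan <- function(x, ...) {
  cat("Variant enrichment scan\n")
  cat(sprintf("  %d variants (%d clinically labeled, %d without imaging data)\n",
              x$n_total, x$n_clinical, x$n_dropped))
  cat(sprintf("  background: %s; alpha = %g; %s Fisher\n",
              x$background, x$alpha, x$alternative))
  cat(sprintf("  global GOF: X^2 = %.3f, df = %d, p = %.3g\n",
              x$gof$statistic, x$gof$parameter, x$gof$p.value))
  sig <- x$results[x$results$significant & !x$results$degenerate, , drop = FALSE]
  if (nrow(sig)) {
    cat("  cells with p < alpha:\n")
    for (j in seq_len(nrow(sig))) {
      cat(sprintf("    %s / %s: %d of %d variants, p = %s\n",
                  sig$phenotype[j], sig$category[j], sig$observed[j],
                  sig$n[j], format_p(sig$p[j])))
    }
  } else {
    cat("  no cell below alpha\n")
  }
  invisible(x)
}

#' @export
summary.enrich_scan <- function(object, ...) {
  # results are ordered phenotype-major, so columns are phenotypes
  wide <- matrix(object$results$p,
                 ncol = length(CLINICAL_PHENOTYPES),
                 dimnames = list(object$composition$category,
                                 CLINICAL_PHENOTYPES))
  structure(list(p_matrix = wide, gof = object$gof, alpha = object$alpha),
            class = "summary.enrich_scan")
}

#' @export
print.summary.enrich_scan <- function(x, ...) {
  cat("p-values (rows: categories; columns: phenotypes)\n")
  disp <- apply(x$p_matrix, 2, format_p)
  rownames(disp) <- rownames(x$p_matrix)
  print(as.data.frame(disp))
  cat(sprintf("global GOF p = %.3g\n", x$gof$p.value))
  invisible(x)
}

#' @export
as.data.frame.enrich_scan <- function(x, ...) x$results

#' @export
plot.enrich_scan <- function(x, ...) {
  obs <- x$gof$observed
  exp <- x$gof$expected
  mat <- rbind(observed = obs, expected = exp)
  colnames(mat) <- x$composition$category
  graphics::barplot(mat, beside = TRUE, legend.text = rownames(mat),
                    las = 2, ylab = "variants",
                    main = "Observed vs composition-proportional expected", ...)
  invisible(x)
}

#' Simulate category counts under the composition null
#'
#' Draws per-phenotype multinomial category counts with probabilities equal
#' to the composition fractions, matching the fitted scan's per-phenotype
#' sample sizes.
#'
#' @param object an `enrich_scan`.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return List of `nsim` matrices (categories x phenotypes) of counts.
#' @importFrom stats simulate
#' @export
simulate.enrich_scan <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cats <- object$composition$category
  f <- object$composition$fraction
  n_m <- stats::setNames(
    object$results$n[match(CLINICAL_PHENOTYPES, object$results$phenotype)],
    CLINICAL_PHENOTYPES)
  lapply(seq_len(nsim), function(i) {
    mat <- sapply(CLINICAL_PHENOTYPES, function(m) {
      as.integer(stats::rmultinom(1, n_m[[m]], f))
    })
    rownames(mat) <- cats
    mat
  })
}
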