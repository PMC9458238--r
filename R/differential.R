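#' Cohen's d effect size
#'
#' Difference between group means divided by the pooled standard deviation:
#' `d = (mean_a - mean_b) / s_pooled`,
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param group_a,group_b Numeric samples, each of size >= 2.
#' @return `d`; `NA` (with a warning) when the pooled SD is zero.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 observations")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) {
    warning("zero pooled standard deviation; d undefined")
    return(NA_real_)
  }
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Cohen's h effect size for two proportions
#'
#' Difference of arcsine-transformed proportions:
#' `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @return `h` in `[-pi, pi]`.
#' @export
cohens_h <- function(p1, p2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("proportions must lie in [0, 1]")
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Magnitude class of an effect size
#'
#' Cohen's conventional thresholds on the absolute value:
#' negligible < 0.2 <= small < 0.5 <= medium < 0.8 <= large.
#'
#' @param effect Numeric effect sizes (d or h).
#' @return Ordered factor of classes.
#' @export
effect_size_class <- function(effect) {
  cut(abs(effect), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE, ordered_result = TRUE)
}

class_threshold <- function(threshold_class = c("medium", "large", "small")) {
  c(small = 0.2, medium = 0.5, large = 0.8)[[match.arg(threshold_class)]]
}

#' Effect-size differential analysis of components
#'
#' Computes Cohen's d for every component between two pixel sets (pixels are
#' the observations) and selects components whose `|d|` reaches the requested
#' magnitude class, optionally restricted to one direction.
#'
#' @param abund Abundance matrix (pixels x components).
#' @param pixels_a,pixels_b Integer or logical pixel indices of the contrast.
#' @param threshold_class `"medium"` (default), `"large"` or `"small"`.
#' @param direction `"both"`, `"up"` (higher in `pixels_a`) or `"down"`.
#' @param contrast Label stored with the table.
#' @return List with `table` (data frame: component, d, class, direction),
#'   `selected` (component ids), and `class_counts` (components per magnitude
#'   class, as used for effect-size heat maps).
#' @export
differential_components <- function(abund, pixels_a, pixels_b,
                                    threshold_class = "medium",
                                    direction = c("both", "up", "down"),
                                    contrast = "A-vs-B") {
  direction <- match.arg(direction)
  abund <- as.matrix(abund)
  a <- abund[pixels_a, , drop = FALSE]
  b <- abund[pixels_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stop("both pixel sets need at least 2 pixels")
  sp2 <- ((na - 1) * col_vars(a) + (nb - 1) * col_vars(b)) / (na + nb - 2)
  d <- ifelse(sp2 > 0, (colMeans(a) - colMeans(b)) / sqrt(sp2), NA_real_)
  ids <- if (!is.null(colnames(abund))) colnames(abund) else
    as.character(seq_len(ncol(abund)))
  tab <- data.frame(component = ids, d = d,
                    class = effect_size_class(d),
                    direction = ifelse(is.na(d), NA_character_,
                                       ifelse(d >= 0, "up", "down")),
                    stringsAsFactors = FALSE)
  thr <- class_threshold(threshold_class)
  sel <- !is.na(d) & abs(d) >= thr
  if (direction == "up") sel <- sel & d > 0
  if (direction == "down") sel <- sel & d < 0
  list(contrast = contrast, table = tab, selected = ids[sel],
       class_counts = table(tab$class))
}

#' Venn region cardinalities of three component sets
#'
#' @param setA,setB,setC Vectors over one component universe.
#' @return Named integer vector of the 7 region sizes
#'   (`A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`).
#' @export
overlap_sets <- function(setA, setB, setC) {
  u <- unique(c(setA, setB, setC))
  a <- u %in% setA; b <- u %in% setB; cc <- u %in% setC
  c(A_only = sum(a & !b & !cc), B_only = sum(!a & b & !cc),
    C_only = sum(!a & !b & cc), AB = sum(a & b & !cc),
    AC = sum(a & !b & cc), BC = sum(!a & b & cc), ABC = sum(a & b & cc))
}

#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided exact p-value: for 2 x 2 tables by hypergeometric summation of
#' tables at most as probable as the observed one; for larger tables by the
#' Freeman-Halton generalization (full enumeration over tables with the
#' observed margins). Tables with more than `max_total` observations must use
#' the seeded Monte Carlo mode.
#'
#' @param table Matrix of nonnegative integer counts, at least 2 x 2.
#' @param max_total Exact-enumeration bound on the table total (default 1e4).
#' @param simulate Use Monte Carlo estimation (`B` draws, seeded).
#' @param B,seed Monte Carlo replicates and seed.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table, max_total = 1e4, simulate = FALSE,
                         B = 1e6, seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (!simulate && sum(table) > max_total)
    stop("table total exceeds the exact enumeration bound; ",
         "use simulate = TRUE for the seeded Monte Carlo mode")
  if (simulate) {
    res <- withr::with_seed(seed,
      fisher.test(table, simulate.p.value = TRUE, B = B))
  } else {
    res <- fisher.test(table, workspace = 2e7)
  }
  res$p.value
}

#' Two-sample Student's t-test
#'
#' Equal-variance two-sided t-test, as used for comparing patient age between
#' outcome groups.
#'
#' @param group_a,group_b Numeric samples.
#' @return List with `statistic`, `df`, `p.value`, `means`.
#' @export
students_t <- function(group_a, group_b) {
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, means = unname(ht$estimate))
}

#' Association between diversity and lymphocytic host response (LHR)
#'
#' Tests whether Simpson diversity increases with the ordered LHR grade:
#' Kruskal-Wallis across categories plus Spearman rank correlation on the
#' ordinal coding; optionally Fisher's exact test of the LHR x outcome-group
#' contingency table.
#'
#' @param diversity Numeric diversity value per patient.
#' @param lhr LHR category per patient; character or factor, coded in the
#'   order `levels` (default weak < intermediate < strong).
#' @param group Optional outcome group per patient (e.g. NED/PD) for the
#'   contingency test.
#' @param levels Ordered category levels.
#' @return List with `kruskal` (statistic, p.value), `spearman` (rho,
#'   p.value), and `fisher_p` when `group` is given.
#' @export
lhr_association <- function(diversity, lhr, group = NULL,
                            levels = c("weak", "intermediate", "strong")) {
  lhr <- factor(lhr, levels = levels, ordered = TRUE)
  if (any(is.na(lhr))) stop("lhr contains values outside the given levels")
  present <- droplevels(lhr)
  if (nlevels(present) < 2L) stop("need at least 2 LHR categories present")
  kw <- kruskal.test(diversity, present)
  if (sd(diversity) == 0) {
    # no variation in the index: rank correlation is identically zero
    spearman <- list(rho = 0, p.value = 1)
  } else {
    sp <- suppressWarnings(
      cor.test(diversity, as.integer(lhr), method = "spearman"))
    spearman <- list(rho = unname(sp$estimate), p.value = sp$p.value)
  }
  out <- list(kruskal = list(statistic = unname(kw$statistic),
                             p.value = kw$p.value),
              spearman = spearman)
  if (!is.null(group))
    out$fisher_p <- fisher_exact(table(droplevels(lhr), group))
  out
}
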