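#' Aggregate repeated measurements to one value per animal
#'
#' Morphometry-style tables carry several measurements per animal (e.g. 10
#' villus lengths per section); downstream statistics use the per-animal
#' arithmetic mean so animals, not measurements, are the replication unit.
#'
#' @param raw data.frame of repeated measurements.
#' @param value name of the measurement column.
#' @param animal name of the animal-id column.
#' @param keep names of grouping columns (genotype, region, ...) carried
#'   through; must be constant within animal.
#' @return data.frame with one row per animal (per `keep` combination):
#'   the kept columns, `n_repeats`, `value` (the mean).
#' @export
aggregate_per_animal <- function(raw, value = "value", animal = "animal_id",
                                 keep = intersect(c("genotype", "region",
                                                    "measure", "group"),
                                                  names(raw))) {
  stopifnot(value %in% names(raw), animal %in% names(raw))
  key <- interaction(raw[c(animal, keep)], drop = TRUE)
  sp <- split(raw, key)
  out <- do.call(rbind, lapply(sp, function(d) {
    cbind(d[1, c(animal, keep), drop = FALSE],
          n_repeats = nrow(d),
          value = mean(d[[value]]))
  }))
  rownames(out) <- NULL
  out
}

#' Mean and standard error of the mean
#'
#' @param x numeric vector with at least 2 values.
#' @return A named list: `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @export
summarize_mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("SEM needs at least 2 values; got ", n)
  list(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n)
}

tukey_table <- function(aov_fit, which) {
  tk <- stats::TukeyHSD(aov_fit, which = which)[[which]]
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(cmp, `[`, character(1), 1),
             group_b = vapply(cmp, `[`, character(1), 2),
             mean_diff = unname(tk[, "diff"]),
             adjusted_p = unname(tk[, "p adj"]),
             row.names = NULL)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard one-way analysis of variance of `value` across `group`, with
#' Tukey honest-significant-difference adjusted p-values for all pairwise
#' group comparisons at `alpha = 0.05`.
#'
#' @param data data.frame with columns named by `value` and `group`.
#' @param value,group column names.
#' @param alpha significance threshold (default 0.05).
#' @return A list of class `stats_result`: `anova` (data.frame of effect,
#'   df, F, p), `tukey` (data.frame group_a, group_b, mean_diff,
#'   adjusted_p), `alpha`, `design`.
#' @export
one_way_anova_tukey <- function(data, value = "value", group = "group",
                                alpha = 0.05) {
  d <- data.frame(value = data[[value]], group = factor(data[[group]]))
  if (nlevels(d$group) < 2L) stop("need at least 2 groups")
  if (any(table(d$group) < 2L)) stop("each group needs n >= 2")
  if (stats::var(d$value) == 0) stop("all values identical; ANOVA degenerate")
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  structure(list(anova = data.frame(effect = "group",
                                    df = an[1, "Df"],
                                    df_resid = an[2, "Df"],
                                    f = an[1, "F value"],
                                    p = an[1, "Pr(>F)"]),
                 tukey = tukey_table(fit, "group"),
                 alpha = alpha, design = "one-way"),
            class = "stats_result")
}

#' Two-way ANOVA (type-II SS) with within-region Tukey comparisons
#'
#' Main effects and interaction of `group` (genotype) and `region` on
#' `value`, using type-II sums of squares (robust to the mild imbalance of
#' unequal group sizes). Tukey HSD is applied to all pairwise group
#' comparisons within each region, mirroring within-region brackets on
#' grouped plots. With a single region level the analysis degenerates to
#' [one_way_anova_tukey].
#'
#' @param data data.frame with `value`, `group` and `region` columns.
#' @param value,group,region column names.
#' @param alpha significance threshold.
#' @return A `stats_result` (see [one_way_anova_tukey]); the Tukey table
#'   gains a `region` column.
#' @export
two_way_anova_tukey <- function(data, value = "value", group = "group",
                                region = "region", alpha = 0.05) {
  d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                  region = factor(data[[region]]))
  if (nlevels(d$region) < 2L)
    return(one_way_anova_tukey(d, "value", "group", alpha))
  cells <- table(d$group, d$region)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: group %s x region %s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  if (any(cells < 2)) stop("each group x region cell needs n >= 2")
  fit <- stats::aov(value ~ group * region, data = d)
  a2 <- car::Anova(stats::lm(value ~ group * region, data = d), type = 2)
  an <- data.frame(effect = c("group", "region", "group:region"),
                   df = a2$Df[1:3],
                   df_resid = a2$Df[4],
                   f = a2$`F value`[1:3],
                   p = a2$`Pr(>F)`[1:3])
  tk <- stats::TukeyHSD(fit, which = "group:region")[["group:region"]]
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  parse_cell <- function(s) strsplit(s, ":", fixed = TRUE)[[1]]
  a <- lapply(vapply(cmp, `[`, character(1), 1), parse_cell)
  b <- lapply(vapply(cmp, `[`, character(1), 2), parse_cell)
  same_region <- vapply(seq_along(a), function(i) a[[i]][2] == b[[i]][2],
                        logical(1))
  tukey <- data.frame(region = vapply(a, `[`, character(1), 2),
                      group_a = vapply(a, `[`, character(1), 1),
                      group_b = vapply(b, `[`, character(1), 1),
                      mean_diff = unname(tk[, "diff"]),
                      adjusted_p = unname(tk[, "p adj"]),
                      row.names = NULL)[same_region, , drop = FALSE]
  rownames(tukey) <- NULL
  structure(list(anova = an, tukey = tukey, alpha = alpha,
                 design = "two-way (type II)"),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("ANOVA (%s), alpha = %g\n", x$design, x$alpha))
  print(x$anova, digits = 4, row.names = FALSE)
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey, digits = 4, row.names = FALSE)
  invisible(x)
}
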