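# Study-level statistics: temporal progression within each group by one-way
# ANOVA with Tukey-Kramer post hoc pairs, genotype contrasts at each age by
# the Mann-Whitney U test, star codes and percent change versus control.

#' Significance star scale
#'
#' p < 0.05 (*), p < 0.01 (**), p < 0.001 (***), p < 0.0001 (****); strict
#' inequalities, `"ns"` otherwise.
#'
#' @return An object of class `significance_scale`.
#' @export
significance_scale <- function() {
  structure(list(thresholds = c(0.05, 0.01, 0.001, 0.0001),
                 stars = c("*", "**", "***", "****"),
                 ns = "ns"),
            class = "significance_scale")
}

#' Star code for a p-value
#'
#' Returns the longest star string whose threshold strictly exceeds the
#' p-value; a p-value exactly at a threshold gets the weaker label (strict
#' `<`), so `star_code(0.05)` is `"ns"`.
#'
#' @param p_value Numeric p-value(s) in `[0, 1]`.
#' @param scale A [significance_scale()].
#' @return Character vector of star codes.
#' @export
star_code <- function(p_value, scale = significance_scale()) {
  if (any(is.na(p_value)) || any(p_value < 0 | p_value > 1)) {
    stop("p_value must lie within [0, 1]")
  }
  vapply(p_value, function(p) {
    hit <- which(p < scale$thresholds)
    if (length(hit) == 0) scale$ns else scale$stars[max(hit)]
  }, character(1))
}

#' Percent change relative to a reference mean
#'
#' `100 * (test - reference) / reference`, with the direction of change.
#'
#' @param reference_mean Reference (control) mean, non-zero.
#' @param test_mean Test-group mean.
#' @return List with `percent_change` and `direction` (`"increase"`,
#'   `"decrease"` or `"none"`).
#' @export
percent_change <- function(reference_mean, test_mean) {
  if (reference_mean == 0) stop("reference mean must be non-zero")
  pc <- 100 * (test_mean - reference_mean) / reference_mean
  dir <- if (pc > 0) "increase" else if (pc < 0) "decrease" else "none"
  list(percent_change = pc, direction = dir)
}

#' Gray tone for schematic intensity rendering
#'
#' Maps a mean intensity on the 0--255 working scale onto the schematic
#' display range (0--250 by default; whiter = brighter), clipping at the
#' range ends. Monotone increasing.
#'
#' @param mean_intensity Intensity in `[0, 255]` (vectorised).
#' @param display_range Two-element display range, default `c(0, 250)`.
#' @return Tone value(s) within `display_range`.
#' @export
gray_tone <- function(mean_intensity, display_range = c(0, 250)) {
  pmin(pmax(mean_intensity, display_range[1]), display_range[2])
}

.result_row <- function(contrast, test, statistic, p_value,
                        percent_change = NA_real_, direction = NA_character_,
                        extra = list()) {
  df <- data.frame(contrast = contrast, test = test, statistic = statistic,
                   p_value = p_value, star = star_code(p_value),
                   percent_change = percent_change, direction = direction,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' One-way ANOVA with Tukey-Kramer post hoc pairs
#'
#' Omnibus F test across ages followed by all pairwise comparisons with the
#' Tukey-Kramer adjustment (valid for unequal group sizes). Degenerate
#' inputs are resolved by limits: all values identical across groups gives
#' F = 0, p = 1; zero within-group variance with unequal means gives
#' p = 0.
#'
#' @param samples_by_age Named list mapping age (or any level label) to a
#'   numeric vector of values; at least 2 levels with at least 2 values
#'   each.
#' @return Data frame of comparison rows: one `"anova"` omnibus row and one
#'   `"tukey_pair"` row per level pair, with statistic, p-value and star.
#' @export
anova_tukey <- function(samples_by_age) {
  if (length(samples_by_age) < 2) {
    stop("insufficient data: need at least 2 groups")
  }
  ns <- vapply(samples_by_age, length, integer(1))
  if (any(ns < 2)) stop("insufficient data: every group needs >= 2 values")
  lev <- names(samples_by_age)
  if (is.null(lev)) lev <- as.character(seq_along(samples_by_age))
  values <- unlist(samples_by_age, use.names = FALSE)
  fac <- factor(rep(lev, ns), levels = lev)
  means <- vapply(samples_by_age, mean, numeric(1))
  ss_within <- sum(vapply(samples_by_age,
                          function(v) sum((v - mean(v))^2), numeric(1)))
  pairs <- utils::combn(lev, 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")

  if (ss_within < .Machine$double.eps * sum(values^2 + 1)) {
    if (max(means) - min(means) < 1e-12) {
      omni <- .result_row("omnibus", "anova", 0, 1)
      pr <- lapply(seq_len(ncol(pairs)), function(j)
        .result_row(pair_names[j], "tukey_pair", 0, 1))
    } else {
      omni <- .result_row("omnibus", "anova", Inf, 0)
      pr <- lapply(seq_len(ncol(pairs)), function(j) {
        d <- abs(means[pairs[2, j]] - means[pairs[1, j]])
        if (d < 1e-12) .result_row(pair_names[j], "tukey_pair", 0, 1)
        else .result_row(pair_names[j], "tukey_pair", Inf, 0)
      })
    }
    return(do.call(rbind, c(list(omni), pr)))
  }

  fit <- stats::aov(values ~ fac)
  tab <- summary(fit)[[1]]
  omni <- .result_row("omnibus", "anova", tab[1, "F value"],
                      tab[1, "Pr(>F)"])
  tk <- stats::TukeyHSD(fit)$fac
  pr <- lapply(rownames(tk), function(nm)
    .result_row(nm, "tukey_pair", tk[nm, "diff"], tk[nm, "p adj"]))
  do.call(rbind, c(list(omni), pr))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The p-value is exact
#' (full enumeration of orderings) when there are no ties and the number of
#' arrangements `choose(n_a + n_b, n_a)` does not exceed `exact_cap`;
#' otherwise the midrank normal approximation with continuity correction is
#' used. The reported statistics satisfy `U_a + U_b = n_a * n_b`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact_cap Maximum number of arrangements for the exact mode
#'   (default 2e5).
#' @return Data frame row with `statistic` (= `U_a`), `u_b`, `p_value`,
#'   `star`, and `exact` (logical).
#' @export
mann_whitney <- function(sample_a, sample_b, exact_cap = 2e5) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("insufficient data: both samples must be non-empty")
  }
  na <- length(sample_a); nb <- length(sample_b)
  if (max(c(sample_a, sample_b)) == min(c(sample_a, sample_b))) {
    # all pooled values identical: no evidence either way
    return(.result_row("a-b", "mann_whitney", na * nb / 2, 1,
                       extra = list(u_b = na * nb / 2, exact = FALSE,
                                    n_a = na, n_b = nb)))
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- !ties && choose(na + nb, na) <= exact_cap
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            exact = exact, correct = TRUE))
  u_a <- unname(wt$statistic)
  out <- .result_row("a-b", "mann_whitney", u_a, unname(wt$p.value),
                     extra = list(u_b = na * nb - u_a, exact = exact,
                                  n_a = na, n_b = nb))
  out
}

#' Run the full study contrast set
#'
#' For every (layer, variable) stratum: temporal progression within each
#' group (one-way ANOVA across ages plus all Tukey-Kramer pairs) and a
#' between-group Mann-Whitney U test at each age, annotated with the percent
#' change of the test group relative to the reference (first) group's mean.
#' Results are ordered deterministically (layer, variable, within-group
#' blocks in group order, then between-group tests by age).
#'
#' @param study Long-format data frame with columns `group`, `age`, `layer`,
#'   `variable`, `value` and (for per-field pooling) `field_id`.
#' @param pooling `"cell"` pools individual cells within each (group, age,
#'   layer) stratum (matching per-cell data points in the study design);
#'   `"field"` first aggregates cells to per-field medians, avoiding
#'   pseudo-replication.
#' @param reference_group Reference level for percent change (default the
#'   first group encountered; the study's control is `"WT"`).
#' @param fdr_adjust Append a Benjamini-Hochberg adjusted p-value column
#'   across the whole contrast list (off by default, mirroring the study's
#'   design of no cross-variable correction).
#' @return Data frame of comparison rows with context columns `layer`,
#'   `variable`, `group`/`age` and the fields of [anova_tukey()] /
#'   [mann_whitney()] rows.
#' @export
run_study_contrasts <- function(study, pooling = c("cell", "field"),
                                reference_group = NULL,
                                fdr_adjust = FALSE) {
  pooling <- match.arg(pooling)
  need <- c("group", "age", "layer", "variable", "value")
  for (column in need) {
    if (!column %in% names(study)) {
      stop("study table schema error: missing column ", column)
    }
  }
  if (pooling == "field") {
    if (!"field_id" %in% names(study)) {
      stop("study table schema error: missing column field_id")
    }
    agg <- stats::aggregate(value ~ group + age + layer + variable +
                              field_id, data = study, FUN = stats::median)
    study <- agg
  }
  groups <- unique(study$group)
  if (is.null(reference_group)) reference_group <- groups[1]
  res <- list()
  for (layer in sort(unique(study$layer))) {
    for (variable in sort(unique(study$variable))) {
      sub <- study[study$layer == layer & study$variable == variable, ]
      if (nrow(sub) == 0) next
      ages <- sort(unique(sub$age))
      # temporal progression within each group
      for (g in groups) {
        sg <- sub[sub$group == g, ]
        by_age <- split(sg$value, factor(sg$age, levels = ages))
        by_age <- by_age[vapply(by_age, length, integer(1)) > 0]
        if (length(by_age) < 2) next
        rows <- anova_tukey(by_age)
        rows$layer <- layer; rows$variable <- variable
        rows$group <- g; rows$age <- NA_integer_
        res[[length(res) + 1]] <- rows
      }
      # genotype contrast at each age
      other <- setdiff(groups, reference_group)
      for (g in other) {
        for (a in ages) {
          va <- sub$value[sub$group == reference_group & sub$age == a]
          vb <- sub$value[sub$group == g & sub$age == a]
          if (length(va) == 0 || length(vb) == 0) next
          row <- mann_whitney(va, vb)
          pc <- percent_change(mean(va), mean(vb))
          row$contrast <- paste(g, "vs", reference_group)
          row$percent_change <- pc$percent_change
          row$direction <- pc$direction
          row$layer <- layer; row$variable <- variable
          row$group <- g; row$age <- a
          res[[length(res) + 1]] <- row
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame())
  }
  all_names <- unique(unlist(lapply(res, names)))
  res <- lapply(res, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[, all_names]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (fdr_adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Simulate a per-cell study table
#'
#' Generates the long-format table of a two-group, multi-age study in which
#' each cell contributes one value per morphometric variable, drawn from a
#' normal distribution per stratum (truncated at zero). Used for
#' calibration and power analyses of the contrast machinery.
#'
#' @param n_per_stratum Cells per (group, age, layer) stratum.
#' @param groups,ages,layers Study design levels.
#' @param variables Named list mapping variable name to `c(mean, sd)`.
#' @param effects Optional data frame with columns `group`, `age`, `layer`,
#'   `variable`, `multiplier`: the stratum mean is multiplied by
#'   `multiplier`.
#' @param seed Integer seed.
#' @return Long-format data frame with `group`, `age`, `layer`, `field_id`,
#'   `variable`, `value`.
#' @export
simulate_study <- function(n_per_stratum = 200L,
                           groups = .groups,
                           ages = .ages,
                           layers = c("OPL", "IPL"),
                           variables = list(
                             soma_area_um2 = c(55, 14),
                             skeleton_area_um2 = c(180, 60),
                             arborization_area_um2 = c(420, 130),
                             fdr = c(1.8, 0.45),
                             mean_intensity_norm = c(120, 25)),
                           effects = NULL, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (g in groups) for (a in ages) for (l in layers) {
    for (v in names(variables)) {
      mu <- variables[[v]][1]; sd <- variables[[v]][2]
      if (!is.null(effects)) {
        hit <- effects$group == g & effects$age == a & effects$layer == l &
          effects$variable == v
        if (any(hit)) mu <- mu * effects$multiplier[which(hit)[1]]
      }
      vals <- pmax(stats::rnorm(n_per_stratum, mu, sd), 1e-6)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, age = a, layer = l,
        field_id = paste(g, a, l, rep(1:4, length.out = n_per_stratum),
                         sep = "_"),
        variable = v, value = vals, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
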