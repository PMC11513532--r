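#' qPCR Ct replicate table
#'
#' Validates and wraps a table of qPCR cycle-threshold (Ct) replicates, one
#' row per (aptamer, tissue, replicate) measurement.
#'
#' @param df Data.frame with columns `aptamer`, `tissue`, `replicate`, `ct`.
#' @return An object of class `qpcr_table` (the validated data.frame).
#' @examples
#' qpcr_table(data.frame(aptamer = "Apt2", tissue = "retina",
#'   replicate = 1:3, ct = c(20.1, 20.3, 19.9)))
#' @export
qpcr_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("aptamer", "tissue", "replicate", "ct") %in% names(df)))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("all Ct values must be positive and finite")
  }
  tissue_compartment(unique(df$tissue))
  n_rep <- tapply(df$ct, interaction(df$aptamer, df$tissue, drop = TRUE),
                  length)
  if (any(n_rep < 3)) {
    warning("fewer than 3 replicates for: ",
            paste(names(n_rep)[n_rep < 3], collapse = ", "))
  }
  df <- as.data.frame(df)
  class(df) <- c("qpcr_table", "data.frame")
  df
}

#' Read a qPCR table from CSV
#'
#' @param path CSV with columns `aptamer,tissue,replicate,ct`.
#' @return A [qpcr_table()].
#' @export
read_qpcr_table <- function(path) {
  qpcr_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-(aptamer, tissue) Ct summary
#'
#' @param table A [qpcr_table()].
#' @return Data.frame with `aptamer`, `tissue`, `mean_ct`, `sd_ct`, `n`.
#' @export
ct_summary <- function(table) {
  agg <- stats::aggregate(ct ~ aptamer + tissue, data = table,
                          FUN = function(x) c(mean(x), sd(x), length(x)))
  out <- data.frame(aptamer = agg$aptamer, tissue = agg$tissue,
                    mean_ct = agg$ct[, 1], sd_ct = agg$ct[, 2],
                    n = as.integer(agg$ct[, 3]), stringsAsFactors = FALSE)
  out[order(out$aptamer, out$tissue), , drop = FALSE]
}

#' Control-normalised delta-Ct
#'
#' The printed convention is `delta Ct = Ct(aptamer) - Ct(control aptamer)`
#' within a tissue (`sign = "as_printed"`). Note that under perfect doubling
#' a lower Ct means more template, so a positive as-printed delta-Ct
#' corresponds to *less* template than the control; the
#' `"abundance_positive"` convention negates the difference so that positive
#' values mean higher abundance. Replicates are averaged to a mean Ct per
#' (aptamer, tissue) before subtraction.
#'
#' @param table A [qpcr_table()].
#' @param aptamer,control_id Aptamer and control-aptamer identifiers.
#' @param tissue Tissue in which to normalise.
#' @param sign `"as_printed"` (default) or `"abundance_positive"`.
#' @return delta-Ct in cycles (single number).
#' @examples
#' tab <- qpcr_table(data.frame(
#'   aptamer = rep(c("Apt2", "Ctrl"), each = 3), tissue = "retina",
#'   replicate = rep(1:3, 2), ct = c(22, 22, 22, 26, 26, 26)))
#' delta_ct(tab, "Apt2", "Ctrl", "retina")
#' @export
delta_ct <- function(table, aptamer, control_id, tissue,
                     sign = c("as_printed", "abundance_positive")) {
  sign <- match.arg(sign)
  mean_ct <- function(id) {
    ct <- table$ct[table$aptamer == id & table$tissue == tissue]
    if (length(ct) == 0L) {
      stop("no Ct measurements for '", id, "' in tissue ", tissue)
    }
    mean(ct)
  }
  d <- mean_ct(aptamer) - mean_ct(control_id)
  if (sign == "abundance_positive") -d else d
}

#' Replicate-level delta-Ct for all aptamers and tissues
#'
#' Pairs replicate i of each aptamer with replicate i of the control aptamer
#' in the same tissue and returns one delta-Ct observation per replicate.
#' This replicate-level representation feeds compartment pooling and the
#' ANOVA.
#'
#' @inheritParams delta_ct
#' @return Data.frame with `aptamer`, `tissue`, `compartment`, `replicate`,
#'   `dct`.
#' @export
delta_ct_replicates <- function(table, control_id,
                                sign = c("as_printed", "abundance_positive")) {
  sign <- match.arg(sign)
  ctrl <- table[table$aptamer == control_id, , drop = FALSE]
  apts <- table[table$aptamer != control_id, , drop = FALSE]
  if (nrow(ctrl) == 0L) stop("control aptamer '", control_id, "' not in table")
  missing_ctrl <- setdiff(unique(apts$tissue), unique(ctrl$tissue))
  if (length(missing_ctrl) > 0L) {
    stop("control aptamer missing in tissue(s): ",
         paste(missing_ctrl, collapse = ", "))
  }
  merged <- merge(apts, ctrl[, c("tissue", "replicate", "ct")],
                  by = c("tissue", "replicate"), suffixes = c("", "_ctrl"))
  if (nrow(merged) < nrow(apts)) {
    warning("dropped ", nrow(apts) - nrow(merged),
            " replicate(s) without a matching control replicate")
  }
  d <- merged$ct - merged$ct_ctrl
  if (sign == "abundance_positive") d <- -d
  out <- data.frame(aptamer = merged$aptamer, tissue = merged$tissue,
                    compartment = tissue_compartment(merged$tissue),
                    replicate = merged$replicate, dct = d,
                    stringsAsFactors = FALSE)
  out[order(out$aptamer, out$tissue, out$replicate), , drop = FALSE]
}

#' Fold difference implied by a delta-Ct magnitude
#'
#' Under perfect per-cycle doubling, one Ct unit corresponds to a 2-fold
#' difference in starting template, so a delta-Ct magnitude of `x` implies a
#' `2^|x|`-fold difference (e.g. 4 units = 16-fold).
#'
#' @param delta_ct_magnitude delta-Ct in cycles (sign ignored).
#' @param efficiency Amplification factor per cycle, default 2 (perfect
#'   doubling).
#' @return The implied fold difference (>= 1).
#' @examples
#' fold_difference(4)  # 16
#' @export
fold_difference <- function(delta_ct_magnitude, efficiency = 2) {
  if (any(!is.finite(delta_ct_magnitude))) stop("delta-Ct must be finite")
  if (efficiency <= 1) stop("efficiency must exceed 1")
  efficiency^abs(delta_ct_magnitude)
}

#' Pool delta-Ct values by compartment
#'
#' Pools all replicate-level delta-Ct observations across a compartment's
#' tissues (the six ocular tissues vs the four well-perfused control
#' organs) and reports mean and SD per (aptamer, compartment).
#'
#' @param replicates Output of [delta_ct_replicates()] (columns `aptamer`,
#'   `compartment`, `dct`).
#' @return Data.frame with `aptamer`, `compartment`, `mean_dct`, `sd_dct`,
#'   `n`.
#' @export
pool_compartments <- function(replicates) {
  stopifnot(all(c("aptamer", "compartment", "dct") %in% names(replicates)))
  if (nrow(replicates) == 0L) stop("no delta-Ct observations to pool")
  agg <- stats::aggregate(dct ~ aptamer + compartment, data = replicates,
                          FUN = function(x) c(mean(x), sd(x), length(x)))
  out <- data.frame(aptamer = agg$aptamer, compartment = agg$compartment,
                    mean_dct = agg$dct[, 1], sd_dct = agg$dct[, 2],
                    n = as.integer(agg$dct[, 3]), stringsAsFactors = FALSE)
  out[order(out$aptamer, out$compartment), , drop = FALSE]
}

#' Two-way ANOVA with Tukey comparisons of delta-Ct values
#'
#' Fits a two-factor fixed-effects ANOVA with interaction,
#' `dct ~ aptamer * compartment`, on replicate-level delta-Ct observations,
#' followed by Tukey honest-significant-difference comparisons over the
#' aptamer-by-compartment cell means (family-wise alpha 0.05). Tukey uses
#' the harmonic-mean cell size for unbalanced designs (as
#' [stats::TukeyHSD()] does).
#'
#' @param replicates Data.frame with columns `aptamer`, `compartment`,
#'   `dct`, one row per replicate observation.
#' @param alpha Significance level for the star tiers, default 0.05.
#' @return A list with `anova` (the ANOVA table as a data.frame), `tukey`
#'   (data.frame of pairwise cell comparisons: `comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `stars`), and `alpha`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(aptamer = c("A", "B"),
#'                  compartment = c("ocular", "control"), rep = 1:4)
#' d$dct <- rnorm(nrow(d))
#' compare_groups(d)
#' @export
compare_groups <- function(replicates, alpha = 0.05) {
  stopifnot(all(c("aptamer", "compartment", "dct") %in% names(replicates)))
  replicates$aptamer <- factor(replicates$aptamer)
  replicates$compartment <- factor(replicates$compartment)
  if (nlevels(replicates$aptamer) < 2L ||
      nlevels(replicates$compartment) < 2L) {
    stop("need at least 2 levels per factor")
  }
  cells <- table(replicates$aptamer, replicates$compartment)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)
    stop("degenerate cells (fewer than 2 replicates): ",
         paste(rownames(cells)[bad[, 1]], colnames(cells)[bad[, 2]],
               sep = ":", collapse = ", "))
  }
  fit <- stats::aov(dct ~ aptamer * compartment, data = replicates)
  atab <- as.data.frame(summary(fit)[[1]])
  atab$term <- trimws(rownames(atab))
  names(atab) <- c("df", "sum_sq", "mean_sq", "f_value", "p_value", "term")
  rownames(atab) <- NULL

  tk <- stats::TukeyHSD(fit, "aptamer:compartment")[[1]]
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  tukey$stars <- significance_stars(tukey$p_adj)
  rownames(tukey) <- NULL
  list(anova = atab[, c("term", "df", "sum_sq", "mean_sq", "f_value",
                        "p_value")],
       tukey = tukey, alpha = alpha)
}

#' Look up one Tukey cell comparison
#'
#' Finds the pairwise comparison between two aptamer-by-compartment cells in
#' a [compare_groups()] result, regardless of the orientation the Tukey
#' table happened to use; the difference (and its interval) is reported as
#' `cell_a - cell_b`.
#'
#' @param result A [compare_groups()] result.
#' @param cell_a,cell_b Cell labels in `"aptamer:compartment"` form.
#' @return One-row data.frame like `result$tukey`.
#' @examples
#' set.seed(1)
#' d <- expand.grid(aptamer = c("A", "B"),
#'                  compartment = c("ocular", "control"), rep = 1:4)
#' d$dct <- rnorm(nrow(d))
#' tukey_comparison(compare_groups(d), "A:ocular", "A:control")
#' @export
tukey_comparison <- function(result, cell_a, cell_b) {
  tk <- result$tukey
  hit <- tk[tk$comparison == paste0(cell_a, "-", cell_b), , drop = FALSE]
  if (nrow(hit) == 0L) {
    hit <- tk[tk$comparison == paste0(cell_b, "-", cell_a), , drop = FALSE]
    if (nrow(hit) == 1L) {
      hit$comparison <- paste0(cell_a, "-", cell_b)
      hit$diff <- -hit$diff
      lwr <- -hit$upr; hit$upr <- -hit$lwr; hit$lwr <- lwr
    }
  }
  if (nrow(hit) != 1L) {
    stop("no comparison between '", cell_a, "' and '", cell_b, "'")
  }
  rownames(hit) <- NULL
  hit
}

#' Significance star tiers
#'
#' Conventional star annotation: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @examples
#' significance_stars(c(0.2, 0.03, 0.00005))
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
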