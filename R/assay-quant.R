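#' Normalize plate-reader viability to vehicle
#'
#' Expresses every well as a percentage of the mean vehicle-well
#' fluorescence of the same plate (vehicle normalization happens within
#' run; pooling across runs comes after), and summarises each condition as
#' mean +/- s.e.m.
#'
#' @param plate data frame with columns `condition` and `fluorescence`.
#' @param vehicle_label vehicle condition label.
#' @return list with `wells` (the input plus `pct_of_vehicle`) and
#'   `summary` (per condition: `mean_pct`, `sem_pct`, `n`).
#' @export
normalize_viability <- function(plate, vehicle_label = "vehicle") {
  stopifnot(all(c("condition", "fluorescence") %in% names(plate)))
  veh <- plate$fluorescence[plate$condition == vehicle_label]
  if (!length(veh)) stop("no vehicle wells labelled `", vehicle_label, "`",
                         call. = FALSE)
  vm <- mean(veh)
  if (vm <= 0) stop("vehicle mean fluorescence must be > 0", call. = FALSE)
  plate$pct_of_vehicle <- 100 * plate$fluorescence / vm
  agg <- split(plate$pct_of_vehicle, plate$condition)
  summary <- data.frame(
    condition = names(agg),
    mean_pct = vapply(agg, mean, numeric(1)),
    sem_pct = vapply(agg, sem, numeric(1)),
    n = vapply(agg, length, integer(1)),
    row.names = NULL)
  list(wells = plate, summary = summary)
}

#' Standard error of the mean
#' @param x numeric vector (n >= 1; the convention is n = independent
#'   experiments, with technical repetitions averaged beforehand).
#' @return `sd(x)/sqrt(length(x))`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Average technical repetitions before inference
#'
#' Collapses repeated measurements to one value per experimental unit, the
#' convention under which s.e.m. and group tests are computed (n =
#' independent experiments).
#'
#' @param values numeric vector.
#' @param unit factor/vector identifying the independent unit of each value.
#' @return data frame `unit`, `value` (mean per unit).
#' @export
average_repetitions <- function(values, unit) {
  stopifnot(length(values) == length(unit))
  agg <- tapply(values, unit, mean)
  data.frame(unit = names(agg), value = as.numeric(agg), row.names = NULL)
}

#' Band density normalized to the loading control
#' @param band band density (AU).
#' @param actin beta-actin density of the same lane (> 0).
#' @return `band / actin`.
#' @export
band_normalize <- function(band, actin) {
  stopifnot(all(band >= 0))
  if (any(actin <= 0)) stop("actin density must be > 0", call. = FALSE)
  band / actin
}

#' GluN2A/GluN2B band-density ratio within lane
#'
#' The within-animal subunit ratio; the common actin normalization cancels
#' but is applied anyway so intermediate values stay auditable.
#'
#' @param glun2a_density,glun2b_density band densities (AU).
#' @param actin lane actin density (> 0).
#' @return the GluN2A/GluN2B ratio.
#' @export
subunit_ratio <- function(glun2a_density, glun2b_density, actin = 1) {
  if (any(glun2b_density <= 0)) {
    stop("GluN2B density must be > 0", call. = FALSE)
  }
  band_normalize(glun2a_density, actin) / band_normalize(glun2b_density, actin)
}

#' Palmitoylation ratio from an APEGS lane
#'
#' In the acyl-PEGyl exchange gel-shift assay, palmitoylated protein is the
#' sum of all bands showing the PEG-dependent molecular-weight shift
#' relative to the -HA (no hydroxylamine) control lane; non-palmitoylated
#' protein is the band matched to the -HA control. The reported ratio is
#' `(palmitoylated / non-palmitoylated) / actin` within lane.
#'
#' @param shifted_bands densities of the shifted bands (AU), possibly empty.
#' @param nonpalm density of the unshifted band (> 0).
#' @param actin lane actin density (> 0).
#' @return list `palm`, `nonpalm`, `ratio`.
#' @export
apegs_ratio <- function(shifted_bands, nonpalm, actin = 1) {
  stopifnot(all(shifted_bands >= 0))
  if (nonpalm <= 0) stop("non-palmitoylated band density must be > 0",
                         call. = FALSE)
  if (actin <= 0) stop("actin density must be > 0", call. = FALSE)
  palm <- sum(shifted_bands)
  list(palm = palm, nonpalm = nonpalm, ratio = (palm / nonpalm) / actin)
}

#' Group comparison stage
#'
#' The thin statistics layer used for every read-out: plain (or Welch)
#' two-group t-tests, one-factor ANOVA with Tukey's post-hoc test, or
#' two-factor ANOVA with interaction and Tukey on the cell means. Per-group
#' mean, s.e.m. and n are always reported.
#'
#' @param data data frame with a numeric `value` column, a `group` column,
#'   and for the two-factor design a second factor column `group2`.
#' @param test `"t"`, `"anova_tukey"` or `"two_way_anova_tukey"`.
#' @param paired pair the two groups by row order (t-test only).
#' @param welch use the Welch correction (t-test only; off by default).
#' @return list with `groups` (per-group summary), `test`, and either
#'   `statistic`/`df`/`p_value` (t) or `anova` plus `tukey` (ANOVA variants).
#' @export
compare_groups <- function(data, test = c("t", "anova_tukey",
                                          "two_way_anova_tukey"),
                           paired = FALSE, welch = FALSE) {
  test <- match.arg(test)
  stopifnot(all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (nlevels(data$group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("need >= 2 replicates per group", call. = FALSE)
  groups <- data.frame(
    group = levels(data$group),
    mean = as.numeric(tapply(data$value, data$group, mean)),
    sem = as.numeric(tapply(data$value, data$group, sem)),
    n = as.integer(sizes))
  if (test == "t") {
    if (nlevels(data$group) != 2) {
      stop("t-test requires exactly 2 groups", call. = FALSE)
    }
    sp <- split(data$value, data$group)
    tt <- stats::t.test(sp[[1]], sp[[2]], paired = paired,
                        var.equal = !welch)
    return(list(test = "t", groups = groups,
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value))
  }
  if (test == "anova_tukey") {
    fit <- stats::aov(value ~ group, data = data)
    tk <- stats::TukeyHSD(fit)$group
    return(list(test = "anova_tukey", groups = groups,
                anova = summary(fit)[[1]],
                tukey = data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL)))
  }
  stopifnot("group2" %in% names(data))
  data$group2 <- factor(data$group2)
  fit <- stats::aov(value ~ group * group2, data = data)
  tk <- stats::TukeyHSD(fit)[["group:group2"]]
  list(test = "two_way_anova_tukey", groups = groups,
       anova = summary(fit)[[1]],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
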