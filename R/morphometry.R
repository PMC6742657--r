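#' Normalize per-cell measures to the control group
#'
#' Divides each measure by the mean of the reference (unstrained control)
#' group within the same donor, so normalized values are fold changes
#' relative to each donor's own control.
#'
#' @param records per-cell tibble with `cell_id`, `donor`, `group` and
#'   measure columns.
#' @param measures character vector of measure column names.
#' @param reference_group control group label.
#' @return records with normalized measure columns.
#' @export
normalize_to_control <- function(records, measures,
                                 reference_group = "control") {
  stopifnot(all(c("donor", "group") %in% names(records)),
            all(measures %in% names(records)))
  if (!reference_group %in% records$group) {
    abort(paste0("reference group '", reference_group, "' absent"))
  }
  for (m in measures) {
    ref_means <- records |>
      filter(.data$group == reference_group) |>
      group_by(.data$donor) |>
      summarise(ref = mean(.data[[m]], na.rm = TRUE), .groups = "drop")
    records <- records |>
      left_join(ref_means, by = "donor") |>
      mutate(!!m := .data[[m]] / .data$ref) |>
      select(-"ref")
  }
  records
}

#' Group/donor linear model for per-cell measures
#'
#' Fits the imaging-statistics model: per-cell log2 measure modeled as an
#' intercept plus treatment-group effects (versus the reference group) and
#' sum-to-zero donor effects,
#' \deqn{y_{gd} = \beta_0 + X_g\beta_g + X_d\beta_d + \varepsilon_{gd},}
#' by least squares. Group effects read as log2 fold changes versus the
#' reference after donor adjustment, with two-tailed p-values. A single
#' donor reduces to the one-way fit. Donor completely confounded with
#' group is an error.
#'
#' @param records per-cell tibble (`cell_id`, `donor`, `group`, measures).
#' @param measure name of the measure column to model.
#' @param reference_group reference group label.
#' @param log2_transform log2-transform the measure before fitting
#'   (default TRUE; set FALSE if the column is already on a log scale).
#' @return a `group_model` object wrapping the `lm` fit; see
#'   [tidy.group_model()].
#' @export
fit_group_donor_model <- function(records, measure,
                                  reference_group = records$group[1],
                                  log2_transform = TRUE) {
  stopifnot(all(c("donor", "group") %in% names(records)))
  if (!measure %in% names(records)) {
    abort(paste0("measure '", measure, "' not present in records"))
  }
  if (!reference_group %in% records$group) {
    abort("reference_group must be one of the groups")
  }
  if (length(unique(records$group)) < 2) abort("need at least 2 groups")
  y <- records[[measure]]
  if (log2_transform) {
    if (any(y <= 0, na.rm = TRUE)) abort("measure must be positive for log2 transform")
    y <- log2(y)
  }
  dat <- tibble(
    y = y,
    group = factor(records$group,
                   levels = c(reference_group,
                              setdiff(unique(records$group), reference_group))),
    donor = factor(records$donor))
  dat <- dat[is.finite(dat$y), , drop = FALSE]
  single_donor <- nlevels(dat$donor) < 2
  fml <- if (single_donor) y ~ group else y ~ group + donor
  ctr <- if (single_donor) NULL else list(donor = "contr.sum")
  fit <- lm(fml, data = dat, contrasts = ctr)
  if (any(is.na(coef(fit)))) {
    tab <- table(dat$group, dat$donor)
    abort(paste0("donor is confounded with group (group x donor table has ",
                 "empty structure: ",
                 paste(rownames(tab)[rowSums(tab > 0) < 2], collapse = ", "),
                 ")"))
  }
  structure(list(model = fit, measure = measure,
                 reference = reference_group,
                 single_donor = single_donor,
                 log2_transform = log2_transform),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat("Group/donor model for ", x$measure,
      " (reference: ", x$reference, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Derived ratio measure per cell
#'
#' Appends the per-cell ratio of two measures (e.g. nuclear to cytoplasmic
#' area) as a new measure column usable by [fit_group_donor_model()].
#' Cells with a zero or missing denominator are excluded with a message.
#'
#' @param records per-cell tibble.
#' @param numerator,denominator measure column names.
#' @param name name of the new column (default
#'   `"<numerator>_to_<denominator>"`).
#' @return records (minus excluded cells) with the ratio column.
#' @export
ratio_metric <- function(records, numerator, denominator,
                         name = paste0(numerator, "_to_", denominator)) {
  stopifnot(all(c(numerator, denominator) %in% names(records)))
  bad <- !is.finite(records[[denominator]]) | records[[denominator]] == 0
  if (any(bad)) {
    inform(paste0(sum(bad), " cell(s) excluded: zero or missing ", denominator))
    records <- records[!bad, , drop = FALSE]
  }
  records[[name]] <- records[[numerator]] / records[[denominator]]
  records
}

#' Log-log scaling regression
#'
#' Simple linear regression of per-cell log2 fold change of a measure on
#' per-cell log2 fold change of expression: the slope is the power-law
#' scaling exponent `b`, reported with its standard deviation. Fitting on
#' per-condition means is available via `mode = "means"` with a grouping
#' column.
#'
#' @param data data frame holding the two variables.
#' @param x,y column names (character) of the predictor and response, in
#'   log2 fold-change units.
#' @param mode `"cells"` (default) fits on the rows as given; `"means"`
#'   averages within levels of `by` first.
#' @param by grouping column for `mode = "means"`.
#' @return a `scaling_fit` list: `slope`, `slope_sd`, `intercept`,
#'   `intercept_sd`, `r_squared`, `n`.
#' @export
loglog_scaling <- function(data, x, y, mode = c("cells", "means"), by = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c(x, y) %in% names(data)))
  dat <- tibble(x = data[[x]], y = data[[y]])
  if (mode == "means") {
    if (is.null(by) || !by %in% names(data)) {
      abort("mode = 'means' needs a grouping column `by`")
    }
    dat$g <- data[[by]]
    dat <- dat |>
      group_by(.data$g) |>
      summarise(x = mean(.data$x, na.rm = TRUE),
                y = mean(.data$y, na.rm = TRUE), .groups = "drop")
  }
  dat <- dat[is.finite(dat$x) & is.finite(dat$y), , drop = FALSE]
  if (nrow(dat) < 3) abort("need at least 3 finite points")
  if (sd(dat$x) == 0) abort("zero variance in x")
  fit <- lm(y ~ x, data = dat)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["x", 1]),
                 slope_sd = unname(sm["x", 2]),
                 intercept = unname(sm["(Intercept)", 1]),
                 intercept_sd = unname(sm["(Intercept)", 2]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(dat), model = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Log-log scaling fit: b = ", signif(x$slope, 3), " +/- ",
      signif(x$slope_sd, 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
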