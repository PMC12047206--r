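#' Construct a validated effect-size table
#'
#' An effect-size table is the central data container: one row per effect
#' size, with the point estimate \code{yi}, its known sampling variance
#' \code{vi}, a study identifier, and optional species, publication year,
#' and shared-subject group labels. Any further columns are treated as
#' moderators (numeric or categorical) available to the location and scale
#' parts of a model. Row order is preserved and defines the order of all
#' downstream vectors and matrices.
#'
#' @param data a data.frame with (at least) columns for the effect estimate,
#'   its sampling variance and the study label.
#' @param effect,var,study,species,year,subject_group,effect_id column names
#'   in \code{data}; \code{species}, \code{year}, \code{subject_group} and
#'   \code{effect_id} are optional (\code{NULL} to omit). When
#'   \code{effect_id} is \code{NULL} sequential labels \code{es1, es2, ...}
#'   are generated.
#' @return an object of class \code{c("effect_table", "data.frame")} with
#'   canonical columns \code{effect_id}, \code{yi}, \code{vi}, \code{study}
#'   (plus \code{species}, \code{year}, \code{subject_group} when supplied)
#'   followed by the moderator columns, and attributes \code{n_effects},
#'   \code{n_studies} and \code{moderators}.
#' @export
effect_table <- function(data, effect = "yi", var = "vi", study = "study",
                         species = NULL, year = NULL, subject_group = NULL,
                         effect_id = NULL) {
  if (!is.data.frame(data)) .stopf("'data' must be a data.frame")
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  need <- c(effect, var, study)
  miss <- setdiff(need, names(data))
  if (length(miss))
    .stopf("required column(s) missing from data: %s",
           paste(miss, collapse = ", "))

  yi <- as.numeric(data[[effect]])
  vi <- as.numeric(data[[var]])
  if (anyNA(yi)) .stopf("effect estimates contain missing values")
  if (anyNA(vi) || any(vi <= 0))
    .stopf("all sampling variances must be present and > 0")
  study_lab <- as.character(data[[study]])
  if (anyNA(study_lab) || any(!nzchar(study_lab)))
    .stopf("every record needs a study label")

  id <- if (is.null(effect_id)) paste0("es", seq_len(nrow(data)))
        else as.character(data[[effect_id]])
  if (anyDuplicated(id))
    .stopf("duplicated effect_id value(s): %s",
           paste(unique(id[duplicated(id)]), collapse = ", "))

  out <- data.frame(effect_id = id, yi = yi, vi = vi, study = study_lab,
                    stringsAsFactors = FALSE)
  opt_cols <- c(species = species, year = year, subject_group = subject_group)
  for (nm in names(opt_cols)) {
    col <- opt_cols[[nm]]
    if (!is.null(col)) {
      if (!col %in% names(data)) .stopf("column '%s' not found", col)
      out[[nm]] <- if (nm == "year") as.integer(data[[col]])
                   else as.character(data[[col]])
    }
  }

  used <- c(effect, var, study, effect_id, unname(opt_cols))
  mods <- setdiff(names(data), used)
  for (m in mods) out[[m]] <- data[[m]]

  structure(out,
            n_effects  = nrow(out),
            n_studies  = length(unique(study_lab)),
            moderators = mods,
            class = c("effect_table", "data.frame"))
}

#' Read an effect-size table from a CSV file
#'
#' Reads a comma-separated file (header required) and validates it with
#' \code{\link{effect_table}}. If the variance column is absent, the
#' sampling variance can be derived from sample sizes for Fisher's
#' z-transformed correlations (\code{es_type = "Zr"}), for which
#' \eqn{v_i = 1/(n_i - 3)}. Other effect-size types must supply the
#' variance directly.
#'
#' @param path path to a CSV file.
#' @param effect,var,study,species,year,subject_group,effect_id column names,
#'   as in \code{\link{effect_table}}.
#' @param es_type optional effect-size type, currently only \code{"Zr"}
#'   triggers variance computation from the sample-size column \code{n}.
#' @param n column holding the (single-sample) sample size, used when
#'   \code{var} is absent and \code{es_type = "Zr"}.
#' @return an \code{\link{effect_table}}.
#' @export
read_effect_table <- function(path, effect = "yi", var = "vi",
                              study = "study", species = NULL, year = NULL,
                              subject_group = NULL, effect_id = NULL,
                              es_type = NULL, n = "n") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!var %in% names(data)) {
    if (identical(es_type, "Zr") && n %in% names(data)) {
      ni <- as.numeric(data[[n]])
      if (anyNA(ni) || any(ni <= 3))
        .stopf("Zr variance needs sample sizes > 3 in column '%s'", n)
      data[[var]] <- 1 / (ni - 3)
    } else {
      .stopf("variance column '%s' absent and cannot be derived (es_type = %s)",
             var, es_type %||% "NULL")
    }
  }
  effect_table(data, effect = effect, var = var, study = study,
               species = species, year = year, subject_group = subject_group,
               effect_id = effect_id)
}

#' Write an effect-size table to CSV
#'
#' Plain \code{write.csv} with canonical column names, so that
#' \code{\link{read_effect_table}} round-trips the table exactly.
#'
#' @param x an \code{\link{effect_table}}.
#' @param path output file path.
#' @export
write_effect_table <- function(x, path) {
  stopifnot(inherits(x, "effect_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf("Effect-size table: %d effect sizes from %d studies\n",
              attr(x, "n_effects"), attr(x, "n_studies")))
  mods <- attr(x, "moderators")
  if (length(mods))
    cat("Moderators:", paste(mods, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Center a covariate
#'
#' Centering (e.g., of publication year) is not essential for model fitting
#' but helps interpretation of intercepts. The center used is recorded in
#' the \code{"center"} attribute so fitted slopes can be mapped back to the
#' original covariate scale.
#'
#' @param values numeric vector (missing values tolerated, ignored when
#'   computing the mean).
#' @param mode \code{"mean"} (default) centers at the mean of the
#'   non-missing values; \code{"value"} centers at \code{center}.
#' @param center numeric center, required for \code{mode = "value"}.
#' @return centered numeric vector with attribute \code{"center"}.
#' @export
center_covariate <- function(values, mode = c("mean", "value"),
                             center = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (all(is.na(values))) .stopf("cannot center an all-missing vector")
  c0 <- switch(mode,
               mean  = mean(values, na.rm = TRUE),
               value = {
                 if (!.is_number(center))
                   .stopf("mode = 'value' needs a numeric 'center'")
                 center
               })
  structure(values - c0, center = c0)
}

#' Effective sample size for bias-test moderators
#'
#' For two-group effect sizes (SMD, lnRR) the effective sample size is
#' \eqn{\tilde n = n_1 n_2 / (n_1 + n_2)}; for single-sample,
#' correlation-type effect sizes (Zr) it is \eqn{\tilde n = n}. The
#' transform \eqn{1/\sqrt{\tilde n}} is the sample-size based axis for
#' small-study (funnel-type) regression tests, preferred over the standard
#' error for SMD-type effect sizes whose point estimates and standard
#' errors are intrinsically correlated.
#'
#' @param design effect-size type: \code{"SMD"}, \code{"lnRR"} (two-group)
#'   or \code{"Zr"} (single-sample).
#' @param n1 first-group (or total, for Zr) sample sizes.
#' @param n2 second-group sample sizes; required for two-group designs.
#' @return a list with components \code{n_eff} and \code{inv_sqrt_n},
#'   vectorized over the inputs.
#' @export
effective_sample_size <- function(design = c("SMD", "lnRR", "Zr"),
                                  n1, n2 = NULL) {
  design <- match.arg(design)
  n1 <- as.numeric(n1)
  if (any(!is.finite(n1)) || any(n1 <= 0))
    .stopf("sample sizes must be positive")
  if (design %in% c("SMD", "lnRR")) {
    if (is.null(n2))
      .stopf("two-group design '%s' needs n2", design)
    n2 <- as.numeric(n2)
    if (any(!is.finite(n2)) || any(n2 <= 0))
      .stopf("sample sizes must be positive")
    n_eff <- n1 * n2 / (n1 + n2)
  } else {
    n_eff <- n1
  }
  list(n_eff = n_eff, inv_sqrt_n = 1 / sqrt(n_eff))
}
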