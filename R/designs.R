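#' Build location and scale design matrices
#'
#' Expands the location and scale model formulas into design matrices with
#' the intercept first. Character and factor moderators are coded as
#' treatment (reference-level dummy) contrasts; the reference is the first
#' level in sorted order unless the column is already a factor with an
#' explicit level order. Rows with missing values in any used moderator are
#' dropped with a warning (no imputation).
#'
#' @param table an \code{\link{effect_table}}.
#' @param location,scale one-sided formulas naming moderators for each
#'   part, e.g. \code{~ habitat + elevation}; default intercept-only.
#' @return a list with elements \code{X_l}, \code{X_s} (design matrices),
#'   \code{study} (factor aligned to rows), \code{species} (factor or
#'   \code{NULL}), \code{table} (the possibly row-subset table) and
#'   \code{keep} (logical row filter applied).
#' @export
build_designs <- function(table, location = ~1, scale = ~1) {
  stopifnot(inherits(table, "effect_table"))
  vars <- union(all.vars(location), all.vars(scale))
  unknown <- setdiff(vars, names(table))
  if (length(unknown))
    .stopf("unknown moderator(s): %s", paste(unknown, collapse = ", "))

  df <- as.data.frame(table)
  for (vn in vars) {
    col <- df[[vn]]
    if (is.character(col)) col <- factor(col, levels = sort(unique(col[!is.na(col)])))
    if (is.factor(col)) {
      col <- droplevels(col)
      if (nlevels(col) < 2L)
        .stopf("moderator '%s' has a single level; cannot form a contrast", vn)
    }
    df[[vn]] <- col
  }

  keep <- rep(TRUE, nrow(df))
  if (length(vars)) {
    keep <- stats::complete.cases(df[, vars, drop = FALSE])
    if (!all(keep))
      .warnf("dropping %d row(s) with missing moderator values", sum(!keep))
  }
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) .stopf("no rows left after dropping missing moderators")

  mk <- function(f) {
    X <- stats::model.matrix(f, data = df)
    # model.matrix puts the intercept first already; keep names tidy
    colnames(X)[colnames(X) == "(Intercept)"] <- "intrcpt"
    X
  }
  X_l <- mk(location)
  X_s <- mk(scale)
  if (!"intrcpt" %in% colnames(X_l) || !"intrcpt" %in% colnames(X_s))
    .stopf("both model parts must include an intercept")

  tab <- table[keep, , drop = FALSE]
  attr_keep <- attributes(table)
  tab <- structure(as.data.frame(tab),
                   n_effects = nrow(tab),
                   n_studies = length(unique(tab$study)),
                   moderators = attr_keep$moderators,
                   class = c("effect_table", "data.frame"))

  list(X_l = X_l, X_s = X_s,
       study = factor(df$study, levels = unique(df$study)),
       species = if (!is.null(df$species))
         factor(df$species, levels = sort(unique(df$species))) else NULL,
       table = tab, keep = keep)
}
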