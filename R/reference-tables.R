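#' Published per-subject voxel-classification percentages
#'
#' Reference per-subject TP/TN/FP/FN percentages from a nine-subject study
#' comparing breath-hold CVR and resting-state CVRe maps: classification of
#' each metric against cortical gray matter within the gray+white VOI
#' (`rs_vs_gm`, `bh_vs_gm`) and the cross-metric classification within the
#' gray-matter VOI (`rs_vs_bh`), each at its optimized threshold(s). The
#' printed accuracy and Dice columns are included so the package's
#' [accuracy()] and [dice()] operations can be checked against them; note
#' the printed values were derived from unrounded per-subject counts, so
#' recomputation from the rounded percentages can differ in the last digit.
#'
#' @return A data frame with columns `comparison`, `subject`, `tp`, `tn`,
#'   `fp`, `fn`, `acc_printed`, `dice_printed` (all percentages).
#' @export
reference_contingency_tables <- function() {
  path <- system.file("extdata", "reference_contingency_tables.csv",
                      package = "cvrconcord", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute accuracy and Dice from the reference percentages
#'
#' Feeds each row of [reference_contingency_tables()] through
#' [contingency_table()], [accuracy()] and [dice()], and appends the
#' recomputed percentage columns `acc` and `dice`.
#'
#' @param df Reference table (defaults to the shipped one).
#' @return The data frame with recomputed `acc` and `dice` columns (percent).
#' @export
reproduce_reference_metrics <- function(df = reference_contingency_tables()) {
  tabs <- lapply(seq_len(nrow(df)), function(i)
    contingency_table(df$tp[i], df$tn[i], df$fp[i], df$fn[i]))
  df$acc <- 100 * vapply(tabs, accuracy, numeric(1))
  df$dice <- 100 * vapply(tabs, dice, numeric(1))
  df
}
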