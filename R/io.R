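#' Read a WST-1 plate CSV
#'
#' Long plate format: columns `drug`, `concentration_uM`, `replicate`,
#' `a450`, `a620`, `well_type` (treated / untreated / blank).
#'
#' @param path CSV path.
#' @return plate data frame ready for [compute_viability()].
#' @export
read_plate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("drug", "concentration_uM", "replicate", "a450", "a620",
           "well_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("plate CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$well_type %in% c("treated", "untreated", "blank")
  if (any(bad)) {
    stop("well_type must be treated/untreated/blank (row ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  df
}

#' Read a qPCR Ct CSV and quantify relative expression
#'
#' The qPCR CSV has columns `sample_id`, `gene` (`MDR1` or `GAPDH`),
#' `condition` (`sample` or `calibrator`), `replicate`, `ct`.
#' `quantify_qpcr()` applies [relative_expression()] per sample, pairing
#' each sample's target/reference triplicates with the calibrator's.
#'
#' @param path CSV path.
#' @return `read_qpcr()`: the validated data frame. `quantify_qpcr()`: one
#'   row per sample with `sample_id`, `delta_delta_ct`, `fold`, `category`.
#' @export
read_qpcr <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "gene", "condition", "replicate", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("qPCR CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$gene %in% c("MDR1", "GAPDH"))) {
    stop("gene must be MDR1 or GAPDH", call. = FALSE)
  }
  if (!all(df$condition %in% c("sample", "calibrator"))) {
    stop("condition must be sample or calibrator", call. = FALSE)
  }
  if (!all(is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("ct values must be finite and > 0", call. = FALSE)
  }
  df
}

#' @rdname read_qpcr
#' @param qpcr data frame from [read_qpcr()].
#' @param thresholds fold thresholds for [categorize_expression()].
#' @export
quantify_qpcr <- function(qpcr, thresholds = c(2, 10)) {
  cal <- qpcr[qpcr$condition == "calibrator", , drop = FALSE]
  if (nrow(cal) == 0L) stop("no calibrator measurements", call. = FALSE)
  ct_cal_t <- cal$ct[cal$gene == "MDR1"]
  ct_cal_r <- cal$ct[cal$gene == "GAPDH"]
  samples <- unique(qpcr$sample_id[qpcr$condition == "sample"])
  rows <- lapply(samples, function(sid) {
    sub <- qpcr[qpcr$sample_id == sid & qpcr$condition == "sample", ,
                drop = FALSE]
    re <- relative_expression(sub$ct[sub$gene == "MDR1"],
                              sub$ct[sub$gene == "GAPDH"],
                              ct_cal_t, ct_cal_r, thresholds = thresholds)
    data.frame(sample_id = sid, delta_delta_ct = re$delta_delta_ct,
               fold = re$fold, category = re$category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
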