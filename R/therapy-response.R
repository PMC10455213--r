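#' Classify the response to induction therapy
#'
#' Applies the standard response criteria assessed after 1-2 courses of
#' induction chemotherapy: complete remission requires bone-marrow blasts
#' below 5%, no circulating blasts, no extramedullary disease, granulocytes
#' at least 1 x 10^9/L and platelets at least 100 x 10^9/L. A patient who
#' had previously achieved remission and shows blasts >= 5%, reappearing
#' circulating blasts or new extramedullary disease is classified as
#' relapse; a patient who never reached remission after the 1-2 induction
#' courses is refractory (primary chemoresistance).
#'
#' @param bm_blasts bone-marrow blast percentage in \[0, 100\].
#' @param circulating_blasts flag: blasts present in peripheral blood.
#' @param extramedullary flag: extramedullary disease present.
#' @param granulocytes granulocyte count, 10^9/L.
#' @param platelets platelet count, 10^9/L.
#' @param prior_cr flag: complete remission previously achieved.
#' @param courses_completed induction courses completed (1 or 2).
#' @return `"remission"`, `"relapse"` or `"refractory"`.
#' @examples
#' classify_therapy_response(3, FALSE, FALSE, 1.5, 120)    # remission
#' classify_therapy_response(7, FALSE, FALSE, 1.5, 120,
#'                           prior_cr = TRUE)              # relapse
#' classify_therapy_response(30, TRUE, FALSE, 0.5, 40,
#'                           courses_completed = 2)        # refractory
#' @export
classify_therapy_response <- function(bm_blasts, circulating_blasts,
                                      extramedullary, granulocytes,
                                      platelets, prior_cr = FALSE,
                                      courses_completed = 1) {
  if (!is.finite(bm_blasts) || bm_blasts < 0 || bm_blasts > 100) {
    stop_field("bm_blasts", "must lie in [0, 100]")
  }
  if (!courses_completed %in% c(1, 2)) {
    stop_field("courses_completed", "must be 1 or 2")
  }
  if (granulocytes < 0 || platelets < 0) {
    stop("cell counts must be >= 0", call. = FALSE)
  }
  cr <- bm_blasts < 5 && !isTRUE(as.logical(circulating_blasts)) &&
    !isTRUE(as.logical(extramedullary)) && granulocytes >= 1 &&
    platelets >= 100
  if (cr) return("remission")
  if (isTRUE(as.logical(prior_cr)) &&
      (bm_blasts >= 5 || isTRUE(as.logical(circulating_blasts)) ||
         isTRUE(as.logical(extramedullary)))) {
    return("relapse")
  }
  "refractory"
}
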