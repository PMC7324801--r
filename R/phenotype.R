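#' Feed conversion ratio (gain/feed)
#'
#' Computes FCR as the weight gain over the testing period divided by the feed
#' consumed: `(endWeight - startWeight) / feedIntake`. Note the convention:
#' this is gain:feed, so *higher* values mean *more* efficient animals — the
#' inverse of the conventional feed:gain ratio that shares the FCR name.
#'
#' @param startWeight,endWeight Weights at test start and end (kg);
#'   `endWeight > startWeight`.
#' @param feedIntake Total feed consumed over the test (kg), strictly
#'   positive.
#' @return Dimensionless gain/feed ratio (vectorized).
#' @examples
#' computeFCR(28, 100, 180) # 0.4
#' @export
computeFCR <- function(startWeight, endWeight, feedIntake) {
    if (any(feedIntake <= 0)) stop("feed intake must be positive")
    if (any(endWeight <= startWeight))
        stop("end weight must exceed start weight")
    (endWeight - startWeight) / feedIntake
}

#' Residual feed intake
#'
#' Fits `DFI = mu + slope * DWG + batch` by least squares (fixed batch
#' effects) and returns the per-animal residuals: feed intake not explained
#' by growth. Lower RFI means more efficient. Residuals sum to zero within
#' each batch (a least-squares identity with intercept and batch dummies).
#'
#' The operation is pure: it fits whatever record set it is given and does
#' not group by breed — per-breed RFI is obtained by calling it per subset.
#'
#' @param records Data frame with columns `sample_id`,
#'   `daily_feed_intake` (kg/day), `daily_weight_gain` (kg/day) and `batch`;
#'   at least 3 records.
#' @return Named numeric vector of residuals, one per sample.
#' @export
computeRFI <- function(records) {
    stopifnot(is.data.frame(records))
    need <- c("sample_id", "daily_feed_intake", "daily_weight_gain", "batch")
    miss <- setdiff(need, names(records))
    if (length(miss))
        stop("records missing columns: ", paste(miss, collapse = ", "))
    if (nrow(records) < 3) stop("need at least 3 records")
    records$batch <- factor(records$batch)
    form <- if (nlevels(records$batch) > 1)
        ~ daily_weight_gain + batch else ~ daily_weight_gain
    X <- model.matrix(form, data = records)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("rank-deficient design; aliased columns: ",
            paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
                collapse = ", "))
    if (nrow(X) <= ncol(X))
        stop("rank-deficient design; too few records (",
            nrow(X), ") for ", ncol(X), " coefficients")
    res <- qr.resid(qrX, records$daily_feed_intake)
    setNames(as.numeric(res), records$sample_id)
}
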