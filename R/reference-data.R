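#' Published reference tables of the Starkrimson maturity study design
#'
#' Plain-text reference values shipped with the package:
#' `reference_postripening()` returns the normalized, direction-adjusted
#' post-ripening quality profile of the four harvest batches together with
#' the reported batch score; `reference_confusions()` returns the reported
#' 3x3 confusion matrices (actual class in rows, over-ripe / ripe / unripe)
#' of the five classifiers under both pretreatments and validation modes,
#' with the reported classification accuracy.
#'
#' These serve as ground truth for the score and accuracy arithmetic and as
#' layout references for the reporting functions; they are not training
#' data.
#'
#' @return `reference_postripening()`: a data frame. `reference_confusions()`:
#'   a list of entries, each with `pretreatment`, `validation`, `model`,
#'   `confusion` (3x3 matrix) and `ca_reported`.
#' @export
reference_postripening <- function() {
  read.csv(system.file("extdata", "postripening_normalized_reference.csv",
                       package = "nirpear"))
}

#' @rdname reference_postripening
#' @export
reference_confusions <- function() {
  df <- read.csv(system.file("extdata", "confusion_reference.csv",
                             package = "nirpear"))
  keys <- unique(df[c("pretreatment", "validation", "model")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$pretreatment == k$pretreatment & df$validation == k$validation &
                df$model == k$model, ]
    sub <- sub[match(c("O", "R", "U"), sub$actual), ]
    cm <- as.matrix(sub[c("O", "R", "U")])
    dimnames(cm) <- list(actual = c("over-ripe", "ripe", "unripe"),
                         predicted = c("over-ripe", "ripe", "unripe"))
    list(pretreatment = k$pretreatment, validation = k$validation,
         model = k$model, confusion = cm, ca_reported = sub$ca_reported[1])
  })
}
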