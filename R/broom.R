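# tidy()/glance() methods for fitted objects.

#' Tidy a cross-validation result
#'
#' @param x A `tmd_cv` from [cross_validate()].
#' @param ... Unused.
#' @return Per-class confusion statistics: one row per organelle class with
#'   counts, MCC, sensitivity and specificity at the reporting threshold.
#' @export
tidy.tmd_cv <- function(x, ...) x$stats

#' @rdname tidy.tmd_cv
#' @return `glance()`: a one-row summary with `accuracy`, `mcc_mean`,
#'   `threshold`, `k`, `n` and `n_classes`.
#' @export
glance.tmd_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, mcc_mean = mean(x$stats$mcc),
         threshold = x$threshold, k = x$k,
         n = nrow(x$scores), n_classes = length(x$classes))
}

#' Tidy a trained network
#'
#' @param x A `tmd_ann` from [ann_train()].
#' @param ... Unused.
#' @return Long tibble of weights: `layer` (`"input"`/`"hidden"`), `from`
#'   (feature, `"bias"`, or hidden unit), `to` (hidden unit or class),
#'   `weight`.
#' @export
tidy.tmd_ann <- function(x, ...) {
  w1 <- as_tibble(x$w_in, .name_repair = ~ paste0("h", seq_along(.x))) %>%
    mutate(from = c("bias", x$features), layer = "input") %>%
    tidyr::pivot_longer(dplyr::starts_with("h"), names_to = "to",
                        values_to = "weight")
  w2 <- as_tibble(x$w_out, .name_repair = ~ x$classes) %>%
    mutate(from = c("bias", paste0("h", seq_len(x$hidden))), layer = "hidden") %>%
    tidyr::pivot_longer(-dplyr::all_of(c("from", "layer")), names_to = "to",
                        values_to = "weight")
  bind_rows(w1, w2) %>% select("layer", "from", "to", "weight")
}

#' @rdname tidy.tmd_ann
#' @return `glance()`: one row with architecture, training configuration
#'   and final training mean squared error.
#' @export
glance.tmd_ann <- function(x, ...) {
  tibble(inputs = nrow(x$w_in) - 1, hidden = x$hidden,
         classes = length(x$classes), rate = x$rate, epochs = x$epochs,
         n_train = x$n_train, final_mse = x$loss[length(x$loss)])
}
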