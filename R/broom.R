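#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained ensemble
#'
#' One row per selected feature with its standardization parameters and
#' selection rank.
#'
#' @param x a `dmn_ensemble`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.dmn_ensemble <- function(x, ...) {
  tibble::tibble(
    feature = x$selected,
    rank = seq_along(x$selected),
    center = unname(x$std$center[x$selected]),
    scale = unname(x$std$scale[x$selected]),
    indicator = unname(x$std$indicator[x$selected])
  )
}

#' @rdname tidy.dmn_ensemble
#' @export
glance.dmn_ensemble <- function(x, ...) {
  tibble::tibble(
    damage_threshold = x$damage_threshold,
    n_members = length(x$members),
    n_features = length(x$selected),
    n_train = x$n_train,
    dataset_balance = x$balance,
    seed = x$seed
  )
}

#' Tidy a leave-one-out evaluation
#'
#' `tidy()` gives one row per metric; `glance()` the one-row metric table.
#'
#' @param x a `dmn_eval`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.dmn_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.dmn_eval
#' @export
glance.dmn_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, method = x$method,
                n_features = length(x$selected))
}

#' Tidy a damage result
#'
#' @param x a `damage_result`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.damage_result <- function(x, ...) {
  tibble::tibble(
    n_dmn_elements = length(x$dmn_element_ids),
    n_damaged = length(x$damaged_element_ids),
    damage_percent = x$damage_percent
  )
}
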