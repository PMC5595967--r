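# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL dose-response fit
#'
#' @param x A `"cc_drfit"`.
#' @param ... Ignored.
#' @return Tibble with one row per model term (`ec50_uM`, `hill`, `top`,
#'   `bottom`) and its `estimate`.
#' @export
tidy.cc_drfit <- function(x, ...) {
  tibble::tibble(
    term = c("ec50_uM", "hill", "top", "bottom"),
    estimate = c(x$ec50, x$hill, x$top, x$bottom)
  )
}

#' One-row summary of a 4PL fit
#'
#' @inheritParams tidy.cc_drfit
#' @return Tibble `ec50_uM`, `hill`, `top`, `bottom`, `rss`, `converged`,
#'   `n`, `ec90_uM`.
#' @export
glance.cc_drfit <- function(x, ...) {
  tibble::tibble(
    ec50_uM = x$ec50, hill = x$hill, top = x$top, bottom = x$bottom,
    rss = x$rss, converged = x$converged, n = x$n,
    ec90_uM = if (isTRUE(x$converged)) effective_concentration(x, 90)
              else NA_real_
  )
}

#' Tidy a cluster tree into its merge list
#'
#' @param x A `"cc_tree"`.
#' @param ... Ignored.
#' @return Tibble `a`, `b`, `height` (negative ids are leaves, positive ids
#'   earlier merges).
#' @export
tidy.cc_tree <- function(x, ...) x$merges

#' One-row summary of a cluster tree
#'
#' @inheritParams tidy.cc_tree
#' @return Tibble `n_leaves`, `n_merges`, `max_height`.
#' @export
glance.cc_tree <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$leaf_order),
    n_merges = nrow(x$merges),
    max_height = max(x$merges$height)
  )
}
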