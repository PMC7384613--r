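# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted framework model
#'
#' One row per model component with its learner family and output
#' dimension.
#'
#' @param x A `framework_model`.
#' @param ... Unused.
#' @return A tibble `component`, `learner`, `task`, `n_outputs`.
#' @method tidy framework_model
#' @export
tidy.framework_model <- function(x, ...) {
  comps <- if (x$species == "ant") {
    list(state = x$state_model, velocity = x$velocity_model)
  } else {
    c(list(state = x$state_model),
      stats::setNames(x$velocity_models,
                      paste0("velocity_state_", names(x$velocity_models))))
  }
  purrr::imap_dfr(comps, function(m, nm) {
    tibble::tibble(component = nm, learner = class(m$spec)[1],
                   task = m$task, n_outputs = m$n_outputs)
  })
}

#' @method glance framework_model
#' @export
glance.framework_model <- function(x, ...) {
  tibble::tibble(
    species = x$species, level = x$level,
    n_states = length(x$state_levels),
    n_animals = if (x$species == "ant") length(x$ids) else NA_integer_,
    lags = if (x$species == "ant") x$cfg$lags else x$lags,
    seed = x$seed
  )
}

#' Tidy a fitted SDE model
#'
#' Per-cell motility and potential values with cell centres and the number
#' of fitting steps observed in each cell.
#'
#' @param x An `sde_model`.
#' @param ... Unused.
#' @return A tibble `cell`, `x`, `y`, `m`, `h`, `n_steps`.
#' @method tidy sde_model
#' @export
tidy.sde_model <- function(x, ...) {
  cc <- cell_centres(x$surfaces)
  n_cell <- attr(x$surfaces, "n_cell") %||% rep(NA_integer_, x$surfaces$J)
  m_vals <- x$surfaces$m
  h_vals <- x$surfaces$h
  tibble::tibble(cell = cc$cell, x = cc$x, y = cc$y,
                 m = m_vals, h = h_vals, n_steps = n_cell)
}

#' @method glance sde_model
#' @export
glance.sde_model <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, n_cells = x$surfaces$J,
    cell_size = x$surfaces$cell_size, n_triples = x$n_triples,
    lambda_m = attr(x$surfaces, "lambda") %||% NA_real_,
    state_model = !is.null(x$state_model)
  )
}

#' Tidy a backward-selected multinomial state model
#'
#' @param x A `multinomial_state_model`.
#' @param ... Unused.
#' @return A tibble of coefficients: `class`, `term`, `estimate`.
#' @method tidy multinomial_state_model
#' @export
tidy.multinomial_state_model <- function(x, ...) {
  cf <- stats::coef(x$fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(x$levels[2], names(cf)))
  tibble::as_tibble(cf, rownames = "class") |>
    tidyr::pivot_longer(-"class", names_to = "term", values_to = "estimate")
}

#' @method glance multinomial_state_model
#' @export
glance.multinomial_state_model <- function(x, ...) {
  tibble::tibble(
    n_retained = length(x$retained), criterion = x$criterion,
    criterion_value = x$criterion_value,
    deviance = stats::deviance(x$fit)
  )
}
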