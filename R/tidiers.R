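#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a quantum walk trajectory
#'
#' Returns the per-step trajectory as a tibble, one row per step, with the
#' per-step stop/continue split (`ps`, `pc`), the unconditional stopping
#' probabilities (`Ps`, `Pc`), the cumulative stop probability, and the
#' mean number of infected agents.
#'
#' @param x A `quantum_walk`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `ps`, `pc`, `Ps`, `Pc`,
#'   `cum_Ps`, `mean_infected`.
#' @exportS3Method generics::tidy
tidy.quantum_walk <- function(x, ...) x$trajectory

#' @rdname tidy.quantum_walk
#' @return `glance()`: a one-row tibble with `t_f`, `converged`,
#'   `epsilon`, `peak_step` (argmax of `Ps`), `max_Ps`, `cum_Ps`, and the
#'   final mean infected count.
#' @exportS3Method generics::glance
glance.quantum_walk <- function(x, ...) {
  tr <- x$trajectory
  tibble::tibble(
    n_agents = x$n_agents,
    t_f = x$t_f,
    converged = x$converged,
    epsilon = x$epsilon,
    peak_step = which.max(tr$Ps),
    max_Ps = max(tr$Ps),
    cum_Ps = tr$cum_Ps[x$t_f],
    final_mean_infected = tr$mean_infected[x$t_f]
  )
}

#' @rdname tidy.quantum_walk
#' @param object A `quantum_walk`.
#' @param quantity Which per-step quantity to draw against the step index.
#' @exportS3Method ggplot2::autoplot
autoplot.quantum_walk <- function(object,
                                  quantity = c("Ps", "mean_infected", "ps",
                                               "cum_Ps"),
                                  ...) {
  quantity <- match.arg(quantity)
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$step, y = .data[[quantity]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "step",
      y = switch(quantity,
                 Ps = "P(stop at step t)",
                 ps = "per-step stop probability",
                 cum_Ps = "cumulative stop probability",
                 mean_infected = "mean number of infected agents")) +
    ggplot2::theme_minimal()
}

#' Tidy a group-decision result
#'
#' @param x A `decision_result`.
#' @param ... Unused.
#' @return `tidy()`: a two-row tibble with the consensus option (0/1) and
#'   its probability; `glance()`: one row with `t_f`, `P0`, `P1`,
#'   `epsilon`.
#' @exportS3Method generics::tidy
tidy.decision_result <- function(x, ...) {
  tibble::tibble(option = c(0L, 1L), probability = c(x$P0, x$P1))
}

#' @rdname tidy.decision_result
#' @exportS3Method generics::glance
glance.decision_result <- function(x, ...) {
  tibble::tibble(n_agents = x$n_agents, t_f = x$t_f, P0 = x$P0, P1 = x$P1,
                 epsilon = x$epsilon)
}

#' @rdname tidy.decision_result
#' @param object A `decision_result`.
#' @exportS3Method ggplot2::autoplot
autoplot.decision_result <- function(object, ...) {
  autoplot.quantum_walk(object$walk, ...)
}

#' Tidy a mid-walk measurement ensemble
#'
#' @param x A `branch_ensemble`.
#' @param ... Unused.
#' @return `tidy()`: one row per collapse outcome with the branch
#'   probability `u`, the branch all-ones probability `v`, and their
#'   product; `glance()`: one row with the classical composite, the
#'   unmeasured baseline, and the interference (baseline minus composite).
#' @exportS3Method generics::tidy
tidy.branch_ensemble <- function(x, ...) x$branches

#' @rdname tidy.branch_ensemble
#' @exportS3Method generics::glance
glance.branch_ensemble <- function(x, ...) {
  tibble::tibble(measure_step = x$measure_step, horizon = x$horizon,
                 composite = x$composite, baseline = x$baseline,
                 interference = x$interference)
}

#' @rdname tidy.branch_ensemble
#' @param object A `branch_ensemble`.
#' @exportS3Method ggplot2::autoplot
autoplot.branch_ensemble <- function(object, ...) {
  df <- object$branches
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$v)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$u)) +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = 2) +
    ggplot2::labs(x = "collapse outcome of the measured pair",
                  y = "all-ones probability at the horizon",
                  fill = "branch\nweight u",
                  caption = "dashed: unmeasured baseline") +
    ggplot2::theme_minimal()
}
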