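#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for target definitions
#'
#' `tidy()` returns one row per target component (HPR, OPR, redefined) with
#' interval counts, covered bases and — when CpG sites were supplied at
#' assembly — CG-site counts. `glance()` returns a one-row summary with the
#' probe mapping rate and what the OPR adds.
#'
#' @param x A `target_definition` from [assemble_target()] /
#'   [redefine_target()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.target_definition <- function(x, ...) {
  s <- x$stats
  out <- tibble(
    component = c("HPR", "OPR", "redefined"),
    n_intervals = c(nrow(x$hpr), nrow(x$opr), nrow(x$redefined)),
    total_bp = c(s$hpr_length, s$opr_length, s$redefined_length)
  )
  if (!is.null(s$target_cg_sites)) {
    out$cg_sites <- c(s$hpr_cg_sites, s$opr_cg_sites, s$target_cg_sites)
  }
  out
}

#' @rdname tidy.target_definition
#' @export
glance.target_definition <- function(x, ...) {
  s <- x$stats
  tibble(
    hpr_bp = s$hpr_length,
    opr_bp = s$opr_length,
    redefined_bp = s$redefined_length,
    opr_added_bp = s$opr_added_bases,
    opr_added_cg_sites = s$opr_added_cg_sites %||% NA_integer_,
    target_cg_sites = s$target_cg_sites %||% NA_integer_,
    n_probes = s$n_probes %||% NA_integer_,
    probe_mapping_rate = s$probe_mapping_rate %||% NA_real_
  )
}

#' Tidiers for methylome summaries
#'
#' `tidy()` returns the per-region-class methylation table; `glance()` a
#' one-row overview (target sites, mean depth, percent of sites at >= 5x,
#' on-target read rate).
#'
#' @param x A `methylome_summary` from [summarize_methylome()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.methylome_summary <- function(x, ...) as_tibble(x$class_summary)

#' @rdname tidy.methylome_summary
#' @export
glance.methylome_summary <- function(x, ...) {
  at5 <- x$depth$coverage$pct_sites[x$depth$coverage$depth == 5]
  tibble(
    n_target_sites = x$depth$n_sites,
    mean_depth = x$depth$mean_depth,
    pct_sites_depth_ge5 = if (length(at5) == 1) at5 else NA_real_,
    on_target_rate = x$on_target_rate
  )
}

#' @export
tidy.depth_profile <- function(x, ...) x$coverage

#' @export
glance.depth_profile <- function(x, ...) {
  tibble(n_sites = x$n_sites, mean_depth = x$mean_depth)
}

#' Plot per-class methylation levels
#'
#' Bars show the per-class mean methylation level, error bars the 95%
#' interval (mean +/- 1.96 sd / sqrt(n)) — the conventional display for
#' "average methylation level by genomic region".
#'
#' @param object A `class_methylation` tibble (or a `methylome_summary`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_methylation <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$mean_level))
  df$region_class <- factor(df$region_class, levels = df$region_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_class,
                                   y = .data$mean_level)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "mean CpG methylation level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methylome_summary <- function(object, ...) {
  autoplot(object$class_summary, ...)
}

#' Plot cumulative depth coverage
#'
#' Percentage of target CpG sites covered at or above each calling-depth
#' threshold.
#'
#' @param object A `depth_profile` from [depth_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object$coverage,
                  ggplot2::aes(x = .data$depth, y = .data$pct_sites)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "calling depth threshold (x)",
                  y = "% of target CpG sites at or above depth") +
    ggplot2::theme_minimal()
}

#' Plot a CpG census
#'
#' CG-site counts per region class, in-target versus in-class.
#'
#' @param object A `cg_census` tibble from [cg_census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cg_census <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$region_class != "TOTAL") %>%
    tidyr::pivot_longer(c("cg_sites_in_class", "cg_sites_in_target"),
                        names_to = "scope", values_to = "cg_sites") %>%
    mutate(scope = ifelse(.data$scope == "cg_sites_in_class",
                          "in class", "in class & target"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_class,
                                   y = .data$cg_sites,
                                   fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CpG sites", fill = NULL) +
    ggplot2::theme_minimal()
}
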