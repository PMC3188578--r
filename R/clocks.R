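# Molecular clock models converting rho to years.
#
# Two clock families are supported:
#   * linear clocks (including the synonymous clock): T = rho *
#     years_per_mutation, with sigma_T = sigma_rho * years_per_mutation;
#   * a purifying-selection-corrected complete-genome clock, in which the
#     expected number of observable substitutions after t years is
#        s(t) = mu_neutral * t + mu_transient * tau * (1 - exp(-t / tau)),
#     i.e. a neutral component accumulating linearly plus a transient
#     component of effectively deleterious changes that arise at rate
#     mu_transient but are removed by selection on a characteristic
#     timescale tau. Ages invert s(t) numerically and sigma_T is
#     propagated through the local derivative (delta method):
#     sigma_T = sigma_rho / s'(T).
#
# Clock constants are configuration data, not hard-coded science: the
# defaults give a long-run complete-genome pace of one substitution per
# 3,624 years and a synonymous pace of one substitution per 7,884 years,
# with a transient excess of one per 12,000 years decaying on an
# 8,000-year selection timescale, but any user-supplied constants work.

#' Construct a clock model
#'
#' @param id short clock identifier used in reports.
#' @param kind `"linear"`, `"soares_synonymous"` (a linear clock counting
#'   only synonymous substitutions) or `"soares_corrected_complete"`.
#' @param years_per_mutation years per counted mutation (linear kinds).
#' @param mu_neutral neutral substitution rate per genome per year
#'   (corrected kind).
#' @param mu_transient transient (selection-exposed) substitution rate per
#'   genome per year (corrected kind).
#' @param tau selection timescale in years (corrected kind).
#' @param exclude descriptors excluded before counting mutations.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(id,
                        kind = c("linear", "soares_synonymous",
                                 "soares_corrected_complete"),
                        years_per_mutation = NULL, mu_neutral = NULL,
                        mu_transient = NULL, tau = NULL,
                        exclude = mt_exclusions("dating")) {
  kind <- match.arg(kind)
  if (kind %in% c("linear", "soares_synonymous")) {
    if (is.null(years_per_mutation) || years_per_mutation <= 0) {
      stop("linear clock needs years_per_mutation > 0")
    }
  } else {
    if (is.null(mu_neutral) || is.null(mu_transient) || is.null(tau)) {
      stop("corrected clock needs mu_neutral, mu_transient and tau")
    }
    if (mu_neutral <= 0 || mu_transient < 0 || tau <= 0) {
      stop("corrected clock constants must be positive")
    }
  }
  structure(list(id = id, kind = kind,
                 years_per_mutation = years_per_mutation,
                 mu_neutral = mu_neutral, mu_transient = mu_transient,
                 tau = tau, exclude = exclude),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Clock", x$id, "(", x$kind, "):",
      if (x$kind == "soares_corrected_complete") {
        sprintf("mu_neutral=%.3g/yr mu_transient=%.3g/yr tau=%g yr",
                x$mu_neutral, x$mu_transient, x$tau)
      } else sprintf("%g years per mutation", x$years_per_mutation), "\n")
  invisible(x)
}

#' Default clock set
#'
#' A purifying-selection-corrected complete-genome clock and a linear
#' synonymous clock (see the package vignette for the parameterisation and
#' defaults).
#'
#' @return named list of `clock_model`s.
#' @export
default_clocks <- function() {
  list(complete = clock_model("complete", "soares_corrected_complete",
                              mu_neutral = 1 / 3624,
                              mu_transient = 1 / 12000, tau = 8000),
       synonymous = clock_model("synonymous", "soares_synonymous",
                                years_per_mutation = 7884))
}

#' Load clock models from a YAML config
#'
#' The config is a map of clock id to fields matching the [clock_model()]
#' arguments.
#'
#' @param path YAML file path.
#' @return named list of `clock_model`s.
#' @export
load_clocks <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(id) {
    f <- cfg[[id]]
    clock_model(id, kind = f$kind,
                years_per_mutation = f$years_per_mutation,
                mu_neutral = f$mu_neutral, mu_transient = f$mu_transient,
                tau = f$tau,
                exclude = if (is.null(f$exclude)) mt_exclusions("dating")
                          else unlist(f$exclude))
  })
  stats::setNames(out, names(cfg))
}

#' Expected observable substitutions after t years
#'
#' @param clock a `clock_model`.
#' @param t age in years (vectorised).
#' @return expected counted substitutions per genome.
#' @export
expected_substitutions <- function(clock, t) {
  if (clock$kind == "soares_corrected_complete") {
    clock$mu_neutral * t +
      clock$mu_transient * clock$tau * (1 - exp(-t / clock$tau))
  } else {
    t / clock$years_per_mutation
  }
}

#' Convert rho to an age estimate
#'
#' Linear clocks multiply by the calibration; the corrected clock inverts
#' its expected-substitution curve numerically and propagates sigma through
#' the local derivative.
#'
#' @param rho_value rho statistic (counted mutations per lineage).
#' @param sigma_rho Saillard standard error of rho.
#' @param clock a `clock_model`.
#' @return object of class `age_estimate`: list with `rho`, `sigma_rho`,
#'   `t_years`, `sigma_t_years`, `clock`.
#' @export
rho_to_time <- function(rho_value, sigma_rho, clock) {
  if (rho_value < 0) stop("rho must be non-negative")
  if (clock$kind == "soares_corrected_complete") {
    if (rho_value == 0) {
      t <- 0
      deriv <- clock$mu_neutral + clock$mu_transient
    } else {
      upper <- rho_value / clock$mu_neutral + 10 * clock$tau
      t <- stats::uniroot(function(x) expected_substitutions(clock, x) -
                            rho_value,
                          lower = 0, upper = upper, tol = 1e-6)$root
      deriv <- clock$mu_neutral + clock$mu_transient * exp(-t / clock$tau)
    }
    sig <- sigma_rho / deriv
  } else {
    t <- rho_value * clock$years_per_mutation
    sig <- sigma_rho * clock$years_per_mutation
  }
  structure(list(rho = rho_value, sigma_rho = sigma_rho, t_years = t,
                 sigma_t_years = sig, clock = clock$id),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("rho = %.3f +/- %.3f  =>  T = %.2f +/- %.2f kya [%s clock]\n",
              x$rho, x$sigma_rho, x$t_years / 1000, x$sigma_t_years / 1000,
              x$clock))
  invisible(x)
}

#' Age table for detected clusters
#'
#' Builds each cluster's genealogy under every clock's counting policy,
#' computes rho and its Saillard standard error, and converts both to years.
#'
#' @param clusters (labelled) list of `star_cluster`s.
#' @param mjg the `mj_graph` the clusters came from.
#' @param vsets named list of full-genome [variant_set]s.
#' @param clocks named list of `clock_model`s.
#' @param ref reference base vector (needed for the synonymous policy).
#' @param annotation gene table for synonymous classification.
#' @return data.frame with one row per cluster x clock: `cluster`,
#'   `haplogroup`, `n`, `rho`, `sigma_rho`, `t_years`, `sigma_t_years`,
#'   `clock`.
#' @export
estimate_ages <- function(clusters, mjg, vsets, clocks = default_clocks(),
                          ref = NULL, annotation = NULL) {
  if (any(vapply(clocks, `[[`, "", "kind") == "soares_synonymous") &&
      is.null(annotation)) {
    annotation <- mt_gene_annotation()
  }
  rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    for (ck in clocks) {
      counted <- if (ck$kind == "soares_synonymous") "synonymous" else "all"
      gen <- cluster_genealogy(cl, mjg, vsets, counted = counted,
                               exclude = ck$exclude, ref = ref,
                               annotation = annotation)
      est <- rho_to_time(rho(gen), saillard_sigma(gen), ck)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl$center, haplogroup = cl$haplogroup, n = gen$n,
        rho = est$rho, sigma_rho = est$sigma_rho, t_years = est$t_years,
        sigma_t_years = est$sigma_t_years, clock = est$clock,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
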