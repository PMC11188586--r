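#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: optic flow
#' window 50 px over 2 resolution levels with a 2 px Gaussian blur before
#' gradient computation; structure-tensor noise scale 1 px and neighborhood
#' scale 5 px with 64-slice chunks; seed density 1 per 100 px; 75-degree
#' termination angle; QuickBundles threshold 50 um with 12-point
#' resampling.
#'
#' @param ... named overrides of any default.
#' @return A named list (class `run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(window = 50L, levels = 2L, blur_sigma = 2,
              sigma_n = 1, sigma_nb = 5, step_size = 64L,
              density = 0.01, rng_seed = 42L, max_angle = 75,
              theta = 50, K = 12L, act_mode = "truncate",
              direction = "forward", gamma = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (n in names(x)) cat(sprintf("  %-10s %s\n", n, format(x[[n]])))
  invisible(x)
}
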