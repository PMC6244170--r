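# Built-in model topologies for the faking-ability analyses.

shape_indicators <- function(jobs = JOBS) {
  c(rbind(paste0("s_wsq_", jobs), paste0("s_neo_", jobs)))
}

elevation_indicators <- function(jobs = JOBS) {
  # the anchor-instrument pilot indicator is excluded from the final
  # elevation measurement model
  setdiff(c(rbind(paste0("e_wsq_", jobs), paste0("e_neo_", jobs))),
          "e_wsq_pilot")
}

#' Built-in model specifications
#'
#' Returns the final model topologies used throughout the pipeline:
#' \describe{
#'   \item{elevation_final}{Single elevation factor on 5 task indicators
#'     (the anchor-instrument pilot task is excluded) with a free error
#'     covariance between the anchor-instrument tour-guide and TV/radio
#'     tasks.}
#'   \item{shape_final}{Single shape factor on all 6 task indicators with
#'     the same error covariance.}
#'   \item{two_factor}{Both factors in one model, correlated.}
#'   \item{cognitive_bifactor}{General factor g on all 11 cognitive
#'     parcels; nested orthogonal gc on the three knowledge parcels and
#'     nested orthogonal ep on the five emotion-perception parcels; the
#'     fluid parcels load on g only, making fluid reasoning the reference
#'     ability of g.}
#'   \item{sem1}{Elevation (final measurement model) regressed on g, gc,
#'     ep.}
#'   \item{sem2}{Shape (final measurement model) regressed on g, gc, ep.}
#' }
#' All factor covariances are fixed to zero unless listed, so the bifactor
#' predictors are mutually orthogonal by construction.
#'
#' @return Named list of \code{\link{fm_spec}} objects.
#' @export
builtin_model_zoo <- function() {
  el_ind <- elevation_indicators()
  sh_ind <- shape_indicators()
  el_ec <- list(c("e_wsq_tour_guide", "e_wsq_tv_radio_announcer"))
  sh_ec <- list(c("s_wsq_tour_guide", "s_wsq_tv_radio_announcer"))
  parc <- default_parcel_loadings()$parcel
  gf <- parc[1:3]; gcp <- parc[4:6]; epp <- parc[7:11]

  bif_factors <- list(g = parc, gc = gcp, ep = epp)

  list(
    elevation_final = fm_spec(
      factors = list(elevation = el_ind), error_cov = el_ec),
    shape_final = fm_spec(
      factors = list(shape = sh_ind), error_cov = sh_ec),
    two_factor = fm_spec(
      factors = list(elevation = el_ind, shape = sh_ind),
      error_cov = c(el_ec, sh_ec),
      factor_cov = list(c("elevation", "shape"))),
    cognitive_bifactor = fm_spec(factors = bif_factors),
    sem1 = fm_spec(
      factors = c(list(elevation = el_ind), bif_factors),
      regressions = list(elevation = c("g", "gc", "ep")),
      error_cov = el_ec),
    sem2 = fm_spec(
      factors = c(list(shape = sh_ind), bif_factors),
      regressions = list(shape = c("g", "gc", "ep")),
      error_cov = sh_ec)
  )
}
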