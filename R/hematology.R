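# Hematology association scan: each of the 15 CBC parameters is tested
# against each feed-efficiency trait with its own mixed model (breed + pen
# fixed, sire random, age + the parameter as covariates), and the gain in
# model R2 over a baseline design-only model is reported.

#' Average daily gain from serial body weights
#'
#' Regresses body weight on day of study with a quadratic polynomial per
#' animal, solves the fitted curve at the trial end and start, and divides
#' the gain by the trial length: ADG = (f(days) - f(0)) / days.  By default
#' the initial weight is the fitted value f(0) (the curve is solved at both
#' endpoints symmetrically); `initial = "raw"` instead subtracts the
#' observed day-0 weight.
#'
#' @param weights long data.frame with columns `animal_id`, `day`, `weight`;
#'   at least 3 distinct days per animal.
#' @param days trial length in days over which gain is averaged.
#' @param initial `"fitted"` (default) or `"raw"`.
#' @return named numeric vector of ADG (kg/d) per animal.
#' @examples
#' w <- data.frame(animal_id = "A1", day = c(0, 1, 21, 42, 63, 84),
#'                 weight = 280 + 0.5 * c(0, 1, 21, 42, 63, 84) +
#'                          0.003 * c(0, 1, 21, 42, 63, 84)^2)
#' adgFromWeights(w)  # (0.5*84 + 0.003*84^2) / 84 = 0.752
#' @export
adgFromWeights <- function(weights, days = 84, initial = c("fitted", "raw")) {
  initial <- match.arg(initial)
  stopifnot(all(c("animal_id", "day", "weight") %in% names(weights)))
  ids <- unique(weights$animal_id)
  adg <- vapply(ids, function(id) {
    w <- weights[weights$animal_id == id, ]
    if (length(unique(w$day)) < 3L)
      stop("animal ", id, ": need >= 3 distinct days for a quadratic fit")
    fit <- stats::lm(weight ~ day + I(day^2), data = w)
    f <- function(d) sum(coef(fit) * c(1, d, d^2))
    start <- if (initial == "fitted") f(0) else w$weight[which.min(w$day)][1]
    (f(days) - start) / days
  }, numeric(1))
  names(adg) <- ids
  adg
}

#' Baseline model R-squared for a trait
#'
#' Fits the design-only mixed model (breed and pen fixed, age covariate,
#' sire random) and returns its conditional R2; the scan reports each CBC
#' parameter's R2 gain over this baseline.
#'
#' @param trait numeric trait vector, aligned with `meta` rows.
#' @param meta herd metadata.
#' @param type passed to [modelR2()].
#' @return R-squared in [0, 1].
#' @export
baselineR2 <- function(trait, meta, type = "conditional") {
  d <- buildDesign(meta, covariates = data.frame(age = meta$age))
  modelR2(fitREML(trait, d), trait, type = type)
}

#' Scan the CBC panel against the feed-efficiency traits
#'
#' One mixed model per (trait, parameter) pair: breed + pen fixed, sire
#' random, age + the parameter as covariates.  Reports the parameter's
#' coefficient (trait units per parameter unit), its standard error, the
#' nominal Wald p-value, the model's conditional R2, and the increment over
#' the trait's baseline R2.  Output is deterministic: trait-major, CBC
#' parameters in instrument-panel order, 3 x 15 = 45 rows.  Parameters that
#' alias with the design (e.g. a copy of age) yield NA coefficient and
#' p-value with a ~0 R2 increment rather than an error.
#'
#' @param traits data.frame with columns `animal_id`, `ADG`, `ADFI`, `GF`.
#' @param cbc CBC panel data.frame (`animal_id` + 15 parameters).
#' @param meta herd metadata; all three inputs must cover the same animals.
#' @param flagThreshold nominal p-value below which a row is flagged.
#' @return data.frame with columns `trait`, `parameter`, `reg`, `se`, `r2`,
#'   `delta_r2`, `p`, `significant`.
#' @export
hemaScan <- function(traits, cbc, meta, flagThreshold = 0.1) {
  missingPar <- setdiff(cbcParameterNames(), names(cbc))
  if (length(missingPar))
    stop("CBC panel is missing parameters: ",
         paste(missingPar, collapse = ", "))
  if (!all(c("ADG", "ADFI", "GF") %in% names(traits)))
    stop("traits must contain ADG, ADFI and GF")
  ord <- match(meta$animal_id, traits$animal_id)
  ordC <- match(meta$animal_id, cbc$animal_id)
  if (anyNA(ord) || anyNA(ordC))
    stop("traits/CBC must cover the same animals as the metadata")
  traits <- traits[ord, ]; cbc <- cbc[ordC, ]

  out <- vector("list", 45L)
  i <- 0L
  for (tr in c("ADG", "ADFI", "GF")) {
    y <- traits[[tr]]
    base <- baselineR2(y, meta)
    for (par in cbcParameterNames()) {
      i <- i + 1L
      d <- buildDesign(meta,
                       covariates = stats::setNames(
                         data.frame(meta$age, cbc[[par]]), c("age", par)))
      fit <- fitREML(y, d)
      if (par %in% d@droppedColumns || !(par %in% names(fit@beta))) {
        r2 <- modelR2(fit, y)
        out[[i]] <- data.frame(trait = tr, parameter = par,
                               reg = NA_real_, se = NA_real_, r2 = r2,
                               delta_r2 = r2 - base, p = NA_real_,
                               significant = FALSE)
      } else {
        r2 <- modelR2(fit, y)
        p <- waldP(fit, par)
        out[[i]] <- data.frame(trait = tr, parameter = par,
                               reg = unname(fit@beta[par]),
                               se = unname(fit@seBeta[par]),
                               r2 = r2, delta_r2 = r2 - base, p = p,
                               significant = p < flagThreshold)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
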