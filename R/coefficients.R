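#' @importFrom stats quantile rnorm rexp runif rbinom var pnorm qnorm qgamma
#'   qt setNames complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

.OUTCOMES <- c("any", "hip")
.SEXES <- c("female", "male")
.VARIANTS <- c("bmd", "weight")
.HORIZONS <- c(5, 10)

# canonicalise "any_osteoporotic" and friends to the internal outcome key
.match_outcome <- function(outcome) {
  outcome <- tolower(as.character(outcome[1L]))
  if (outcome %in% c("any", "any_osteoporotic", "osteoporotic")) return("any")
  if (outcome == "hip") return("hip")
  stop("unknown outcome '", outcome, "'; use 'hip' or 'any' (non-vertebral osteoporotic)",
       call. = FALSE)
}

.match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  out <- ifelse(sex %in% c("female", "f", "women", "woman"), "female",
                ifelse(sex %in% c("male", "m", "men", "man"), "male", NA))
  if (anyNA(out)) stop("sex must be 'female' or 'male'", call. = FALSE)
  out
}

.block_key <- function(outcome, sex, variant) paste(outcome, sex, variant, sep = "_")

#' Load a fracture-risk coefficient document
#'
#' Parses a versioned, human-readable YAML document holding one coefficient
#' block per (outcome, sex, variant) combination, each with category scores
#' for prior fractures and falls, a centring constant for the linear
#' predictor, and baseline survival at the 5- and 10-year horizons. The
#' document also carries the young-adult femoral-neck reference (mean and SD
#' in g/cm^2, per sex) used to interconvert BMD and T-score.
#'
#' The loader is strict: a document missing any (outcome, sex, variant,
#' horizon) block, or containing non-numeric or out-of-range values, is
#' rejected with an error naming the offending block. Baseline survivals
#' must satisfy `0 < s0[10] <= s0[5] < 1`, which guarantees that every
#' prediction lies strictly inside (0, 1) and that 10-year risk is at least
#' the 5-year risk for the same profile.
#'
#' @param path Path to the YAML coefficient document.
#' @return An object of class `garvan_coefficients`: a list with elements
#'   `version`, `source`, `tscore_reference` and `blocks`.
#' @seealso [garvan_coefficients()] for the coefficient set shipped with the
#'   package, [write_coefficients()] for the inverse operation.
#' @export
load_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient document not found: ", path, call. = FALSE)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("coefficient document '", path,
                             "' failed to parse: ", conditionMessage(e), call. = FALSE)
  )
  coefs <- .validate_coefficients(doc, where = path)
  coefs$path <- path
  coefs$checksum <- unname(tools::md5sum(path))
  coefs
}

.validate_coefficients <- function(doc, where = "coefficient document") {
  if (!is.list(doc)) stop(where, ": not a key/value document", call. = FALSE)
  if (is.null(doc$version) || !nzchar(doc$version))
    stop(where, ": missing version string", call. = FALSE)
  ref <- doc$tscore_reference
  for (sex in .SEXES) {
    r <- ref[[sex]]
    if (is.null(r) || !is.numeric(r$mean) || !is.numeric(r$sd) || r$sd <= 0)
      stop(where, ": invalid tscore_reference for ", sex, call. = FALSE)
  }
  blocks <- doc$blocks
  if (!is.list(blocks)) stop(where, ": no coefficient blocks", call. = FALSE)

  grid <- expand.grid(outcome = .OUTCOMES, sex = .SEXES, variant = .VARIANTS,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    key <- .block_key(grid$outcome[i], grid$sex[i], grid$variant[i])
    bl <- blocks[[key]]
    label <- paste(grid$sex[i],
                   ifelse(grid$outcome[i] == "any", "any-osteoporotic", "hip"),
                   grid$variant[i])
    if (is.null(bl))
      stop(where, ": coefficient block missing for ", label, call. = FALSE)
    dens_key <- if (grid$variant[i] == "bmd") "tscore" else "weight"
    needed <- c("age", dens_key, "prior_fracture", "falls", "lp_center", "s0")
    for (k in needed) {
      if (is.null(bl[[k]]))
        stop(where, ": block ", label, " is incomplete: missing '", k, "'", call. = FALSE)
    }
    num <- c(bl$age, bl[[dens_key]], bl$prior_fracture, bl$falls, bl$lp_center)
    if (!is.numeric(num) || anyNA(num) || any(!is.finite(num)))
      stop(where, ": block ", label, " contains a malformed number", call. = FALSE)
    if (length(bl$prior_fracture) != 4L || length(bl$falls) != 3L)
      stop(where, ": block ", label,
           " must score prior fractures 0-3+ and falls 0-2+", call. = FALSE)
    for (h in .HORIZONS) {
      s <- bl$s0[[as.character(h)]]
      if (is.null(s) || !is.numeric(s) || is.na(s))
        stop(where, ": block ", label, " missing baseline survival at horizon ",
             h, " years", call. = FALSE)
      if (s <= 0 || s >= 1)
        stop(where, ": block ", label, " baseline survival at ", h,
             " years outside (0, 1)", call. = FALSE)
    }
    if (bl$s0[["10"]] > bl$s0[["5"]])
      stop(where, ": block ", label,
           " has 10-year baseline survival above the 5-year value", call. = FALSE)
  }
  structure(
    list(version = doc$version,
         source = if (is.null(doc$source)) "" else doc$source,
         model_form = doc$model_form,
         tscore_reference = ref,
         blocks = blocks),
    class = "garvan_coefficients"
  )
}

#' Coefficient set shipped with the package
#'
#' Convenience loader for the synthetic coefficient document installed under
#' `extdata`. The set is synthetic: it reproduces the structure of the
#' Garvan fracture-risk nomograms (Cox linear predictor, category scores,
#' baseline survival exponentiation) with plausible literature-scale hazard
#' ratios, not the published coefficients themselves.
#'
#' @return A `garvan_coefficients` object.
#' @export
garvan_coefficients <- function() {
  load_coefficients(
    system.file("extdata", "garvan_synthetic_coefficients_v1.yaml",
                package = "garvanval", mustWork = TRUE))
}

#' Write a coefficient document
#'
#' Serialises a `garvan_coefficients` object back to YAML so that a
#' document round-trips through [load_coefficients()] unchanged (version,
#' reference constants and every block).
#'
#' @param coefficients A `garvan_coefficients` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "garvan_coefficients"))
  doc <- list(version = coefficients$version,
              source = coefficients$source,
              model_form = coefficients$model_form,
              tscore_reference = coefficients$tscore_reference,
              blocks = coefficients$blocks)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.garvan_coefficients <- function(x, ...) {
  cat("Fracture-risk coefficient set, version", x$version, "\n")
  cat("  blocks:", length(x$blocks),
      "(outcome {hip, any} x sex x variant {bmd, weight})\n")
  cat("  horizons: 5 and 10 years\n")
  if (!is.null(x$checksum)) cat("  md5:", x$checksum, "\n")
  invisible(x)
}

#' Convert femoral-neck BMD to T-score and back
#'
#' Uses the young-adult reference mean and SD carried in the coefficient
#' document (`t = (bmd - mean) / sd`), per sex. Reference constants depend
#' on the densitometer's reference population, which is why they live in
#' the coefficient document rather than in code.
#'
#' @param bmd,tscore Numeric vectors (g/cm^2 and SD units respectively).
#' @param sex `"female"` or `"male"` (vector recycled against the values).
#' @param coefficients A `garvan_coefficients` object.
#' @return Numeric vector of the converted scale.
#' @export
bmd_to_tscore <- function(bmd, sex, coefficients = garvan_coefficients()) {
  sex <- .match_sex(sex)
  ref <- coefficients$tscore_reference
  m <- vapply(sex, function(s) ref[[s]]$mean, numeric(1))
  s <- vapply(sex, function(s) ref[[s]]$sd, numeric(1))
  unname((bmd - m) / s)
}

#' @rdname bmd_to_tscore
#' @export
tscore_to_bmd <- function(tscore, sex, coefficients = garvan_coefficients()) {
  sex <- .match_sex(sex)
  ref <- coefficients$tscore_reference
  m <- vapply(sex, function(s) ref[[s]]$mean, numeric(1))
  s <- vapply(sex, function(s) ref[[s]]$sd, numeric(1))
  unname(tscore * s + m)
}
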