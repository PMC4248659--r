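# Parameter handling: construction, validation, (de)serialization.

# Canonical parameter order used throughout the package (and by the compiled
# right-hand side).  All concentrations molar, rates per hour, X in g/L.
.param_names <- c(
  "Km_LP", "Kcat_LP", "Km_GAL", "Kcat_GAL", "Km_GLYC", "Vmax_GLYC",
  "Km_LDH", "Vmax_LDH", "K_LS", "d_LS", "K_LZ", "d_LZ", "K_LR", "d_LR",
  "d_M", "d_N", "GR", "G", "n", "Kb", "V0", "V1", "V2", "T_max", "S",
  "Ks", "K_LA", "mu_max", "pH_threshold", "c0", "c1", "c2",
  "f_conv", "pyr_per_glc"
)

.flag_names <- c("strict_as_printed", "repression_form")

# Parameters that must be strictly positive (rate and affinity constants).
.strictly_positive <- c(
  "Km_LP", "Kcat_LP", "Km_GAL", "Kcat_GAL", "Km_GLYC", "Vmax_GLYC",
  "Km_LDH", "Vmax_LDH", "K_LS", "d_LS", "K_LZ", "d_LZ", "d_LR",
  "d_M", "d_N", "GR", "G", "n", "T_max", "S", "Ks", "K_LA", "mu_max"
)

#' Model parameters for the lactic-acid fermentation model
#'
#' Builds a validated parameter set for the coupled metabolism / gene
#' regulation model.  Defaults are the published literature values for
#' *L. bulgaricus* growing on lactose in milk: Michaelis-Menten constants
#' for lactose permease (LacS), beta-galactosidase (LacZ), glycolysis and
#' lactate dehydrogenase (LDH); synthesis and decay constants for the
#' lacSZ/lacR expression cascade; Monod growth constants with lactic-acid
#' product inhibition; and the pH-induced promoter switch.
#'
#' The milk-buffering constants `c0`, `c1`, `c2` (pH = c0 - c1*LA + c2*LA^2)
#' are a package assumption: no published values exist for them, so the
#' defaults (6.7, 24, 30) describe fresh milk at pH 6.7 acidifying
#' monotonically to about pH 4.6 at 0.1 M lactic acid.  Replace them with
#' values from [fit_pH_curve()] on your own titration data where available.
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @param strict_as_printed logical; if `TRUE` the net lacSZ transcription
#'   term `V2*G - T_max*S*LR/(1+S*LR)*G` is used exactly as written even
#'   when negative, which can drive the mRNA pool N below zero.  The default
#'   (`FALSE`) floors the net production at zero so repression can silence
#'   but not destroy mRNA.
#' @param repression_form `"printed"` (subtractive repression term, the
#'   default) or `"hill"` (production `T_max*G/(1+S*LR)`, a maximal rate
#'   divided down by repressor).  The hill form changes the basal
#'   (repressor-free) transcription rate from `V2*G` to `T_max*G` and is
#'   provided for structural comparison only.
#'
#' @return an object of class `lacferm_params`: a named list of numeric
#'   parameters plus the two structural flags.
#'
#' @details Parameter glossary (units):
#' \describe{
#'   \item{Km_LP, Kcat_LP}{lactose permease Michaelis constant (M) and
#'     turnover (1/h); transport is reversible, the same constants govern
#'     influx and efflux.}
#'   \item{Km_GAL, Kcat_GAL}{beta-galactosidase constants for lactose
#'     hydrolysis.}
#'   \item{Km_GLYC, Vmax_GLYC}{lumped glycolysis (glucose to pyruvate).}
#'   \item{Km_LDH, Vmax_LDH}{lactate dehydrogenase (pyruvate to lactate).}
#'   \item{K_LS, d_LS, K_LZ, d_LZ}{synthesis (per mRNA) and decay constants
#'     of LacS and LacZ proteins (1/h).}
#'   \item{K_LR, d_LR}{same for the LacR repressor; K_LR stands in for the
#'     ribosome-binding-site strength of the engineered lacR gene.}
#'   \item{d_M, d_N}{decay constants of the lacR and lacSZ mRNAs (1/h).}
#'   \item{GR, G}{lacR and lacSZ gene concentrations (M).}
#'   \item{n, pH_threshold}{steepness and threshold of the pH-induced
#'     promoter switch F(pH) = 1 - tanh(n*(pH - threshold)).}
#'   \item{Kb}{LacR-lactose binding rate constant (1/(M h)).}
#'   \item{V0, V1}{basal and pH-induced lacR transcription rates (1/h);
#'     V0 and V1 characterise the engineered promoter.}
#'   \item{V2, T_max, S}{basal lacSZ transcription rate, maximal lacSZ
#'     transcription rate, and sensitivity of lacSZ transcription to
#'     repressor (S has units 1/M so S*LR is dimensionless).}
#'   \item{Ks, K_LA, mu_max}{Monod constant on extracellular lactose (M),
#'     lactic-acid concentration that fully arrests growth (M), maximum
#'     specific growth rate (1/h).}
#'   \item{c0, c1, c2}{milk pH-buffering curve constants.}
#'   \item{f_conv}{fraction of LDH flux appearing as lactic acid; 0.8,
#'     since homofermentation converts 80-90 percent of sugar carbon in
#'     practice.}
#'   \item{pyr_per_glc}{pyruvate per glucose through glycolysis (2).}
#' }
#'
#' @examples
#' p <- lacferm_params()
#' p$mu_max
#' p2 <- lacferm_params(V1 = 21, K_LR = 1128)
#' @export
lacferm_params <- function(..., strict_as_printed = FALSE,
                           repression_form = c("printed", "hill")) {
  repression_form <- match.arg(repression_form)
  p <- list(
    Km_LP = 2.6e-4, Kcat_LP = 1.29e5,
    Km_GAL = 9.8e-4, Kcat_GAL = 1.65e5,
    Km_GLYC = 1e-4, Vmax_GLYC = 143.82,
    Km_LDH = 0.1, Vmax_LDH = 307.08,
    K_LS = 564, d_LS = 0.6,
    K_LZ = 1.13e3, d_LZ = 0.6,
    K_LR = 564, d_LR = 0.6,
    d_M = 41.58, d_N = 41.58,
    GR = 2.5e-9, G = 2.5e-9,
    n = 1, Kb = 7.2e4,
    V0 = 1, V1 = 20, V2 = 3.5,
    T_max = 6e4, S = 1000,
    Ks = 9.82e-3, K_LA = 0.448, mu_max = 0.8,
    pH_threshold = 5.5,
    c0 = 6.7, c1 = 24, c2 = 30,
    f_conv = 0.8, pyr_per_glc = 2
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), .param_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p$strict_as_printed <- isTRUE(strict_as_printed)
  p$repression_form <- repression_form
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks completeness, finiteness, the positivity constraints on rate and
#' affinity constants, and `f_conv` in (0, 1].
#'
#' @param p a list with the fields of [lacferm_params()].
#' @return the validated object, classed `lacferm_params`.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.param_names, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  num <- vapply(p[.param_names], as.numeric, numeric(1))
  if (any(!is.finite(num)))
    stop("non-finite parameter(s): ",
         paste(.param_names[!is.finite(num)], collapse = ", "))
  bad <- .strictly_positive[num[.strictly_positive] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  neg <- c("K_LR", "Kb", "V0", "V1", "V2")
  bad2 <- neg[num[neg] < 0]
  if (length(bad2))
    stop("parameter(s) must be nonnegative: ", paste(bad2, collapse = ", "))
  if (num[["f_conv"]] <= 0 || num[["f_conv"]] > 1)
    stop("f_conv must lie in (0, 1]")
  if (num[["pyr_per_glc"]] <= 0)
    stop("pyr_per_glc must be positive")
  p[.param_names] <- as.list(num)
  if (is.null(p$strict_as_printed)) p$strict_as_printed <- FALSE
  if (is.null(p$repression_form)) p$repression_form <- "printed"
  if (!p$repression_form %in% c("printed", "hill"))
    stop("repression_form must be 'printed' or 'hill'")
  structure(p[c(.param_names, .flag_names)], class = "lacferm_params")
}

#' Modify selected parameters
#'
#' @param p a `lacferm_params` object.
#' @param ... named numeric replacements (unknown names error).
#' @return a revalidated `lacferm_params` object.
#' @export
update_params <- function(p, ...) {
  dots <- list(...)
  if (!length(dots)) return(p)
  if (is.null(names(dots)) || any(!nzchar(names(dots))))
    stop("all replacements must be named")
  unknown <- setdiff(names(dots), c(.param_names, .flag_names))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_params(p)
}

#' @export
print.lacferm_params <- function(x, ...) {
  cat("Fermentation model parameters (", length(.param_names),
      " constants)\n", sep = "")
  num <- unlist(x[.param_names])
  print(num)
  cat("strict_as_printed:", x$strict_as_printed,
      "| repression_form:", x$repression_form, "\n")
  invisible(x)
}

#' Read a parameter configuration from JSON or YAML
#'
#' Keys must match the field names of [lacferm_params()]; missing keys take
#' their defaults, unknown keys are an error.  The file may also carry the
#' structural flags `strict_as_printed` and `repression_form`.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a `lacferm_params` object.
#' @export
read_params <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config extension: ", ext)
  )
  params_from_list(cfg)
}

# Build a parameter object from a plain named list (config file contents).
params_from_list <- function(cfg) {
  stopifnot(is.list(cfg))
  flags <- list(
    strict_as_printed = isTRUE(cfg$strict_as_printed),
    repression_form = if (is.null(cfg$repression_form)) "printed"
                      else cfg$repression_form
  )
  cfg <- cfg[setdiff(names(cfg), .flag_names)]
  unknown <- setdiff(names(cfg), .param_names)
  if (length(unknown))
    stop("unknown parameter key(s) in config: ",
         paste(unknown, collapse = ", "))
  do.call(lacferm_params,
          c(cfg, list(strict_as_printed = flags$strict_as_printed,
                      repression_form = flags$repression_form)))
}

#' Write a parameter set to JSON
#'
#' @param p a `lacferm_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "lacferm_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
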