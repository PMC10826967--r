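# Single-cell parameter set for the lactotroph model.

# column order of the parameter matrix handed to the compiled integrator
PAR_COLS <- c("C_m", "g_Kdr", "g_Ca", "g_L", "g_SK", "g_BK",
              "V_Ca", "V_K", "V_L", "tau_n", "tau_b",
              "nu_n", "nu_m", "nu_b", "l_n", "l_m", "l_b",
              "alpha", "f_c", "k_c", "k_SK")

#' Parameters of one pituitary lactotroph model cell
#'
#' Returns the full parameter set of the conductance-based lactotroph model.
#' Defaults are the reference values of the intrinsic burster; an intrinsic
#' spiker is obtained by setting `g_BK = 0`.
#'
#' @param ... named overrides of individual parameters.
#'
#' @return An object of class `cell_params`: a named list with entries
#'   `C_m` (membrane capacitance, pF), `g_Kdr`, `g_Ca`, `g_L`, `g_SK`, `g_BK`
#'   (maximal conductances, nS), `V_Ca`, `V_K`, `V_L` (reversal potentials, mV),
#'   `tau_n`, `tau_b` (activation time constants, ms), `nu_n`, `nu_m`, `nu_b`
#'   (half-activation voltages, mV), `l_n`, `l_m`, `l_b` (slope factors, mV),
#'   `alpha` (current-to-concentration conversion, uM/fC), `f_c` (free-calcium
#'   fraction), `k_c` (calcium removal rate, 1/ms) and `k_SK` (SK
#'   half-activation calcium, uM).
#'
#' @examples
#' p <- cell_params()            # intrinsic burster
#' s <- cell_params(g_BK = 0)    # intrinsic spiker
#' @export
cell_params <- function(...) {
  p <- list(
    C_m = 5, g_Kdr = 2.5, g_Ca = 2.1, g_L = 0.2, g_SK = 2, g_BK = 1,
    V_Ca = 60, V_K = -75, V_L = -50,
    tau_n = 30, tau_b = 5,
    nu_n = -5, nu_m = -20, nu_b = -5,
    l_n = 10, l_m = 12, l_b = 2,
    alpha = 0.0015, f_c = 0.005, k_c = 0.12, k_SK = 0.4
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

#' @rdname cell_params
#' @export
burster_params <- function(...) cell_params(g_BK = 1, ...)

#' @rdname cell_params
#' @export
spiker_params <- function(...) cell_params(g_BK = 0, ...)

validate_cell_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter ", nm, " must be a finite scalar")
  g <- c("g_Kdr", "g_Ca", "g_L", "g_SK", "g_BK")
  if (any(unlist(p[g]) < 0)) stop("conductances must be >= 0")
  if (p$C_m <= 0) stop("C_m must be positive")
  if (p$tau_n <= 0 || p$tau_b <= 0) stop("time constants must be positive")
  if (p$l_n <= 0 || p$l_m <= 0 || p$l_b <= 0) stop("slope factors must be positive")
  if (p$f_c <= 0 || p$f_c > 1) stop("f_c must be in (0, 1]")
  if (p$k_SK <= 0) stop("k_SK must be positive")
  invisible(p)
}

#' Is a parameter set an intrinsic burster?
#'
#' A cell with `g_BK > 0` is an intrinsic burster; `g_BK = 0` defines an
#' intrinsic spiker.
#'
#' @param p a `cell_params` object.
#' @return logical flag.
#' @export
is_burster <- function(p) p$g_BK > 0

#' Read and write cell parameters as JSON
#'
#' Parameters are stored as a flat JSON object keyed by the model symbol names
#' (`C_m`, `g_Kdr`, ..., `k_SK`). Keys missing from the file fall back to the
#' reference burster values.
#'
#' @param p a `cell_params` object.
#' @param path file path.
#' @return `read_cell_params` returns a `cell_params` object;
#'   `write_cell_params` returns `path` invisibly.
#' @export
write_cell_params <- function(p, path) {
  stopifnot(inherits(p, "cell_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_params
#' @export
read_cell_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cell_params, as.list(x))
}

# parameter matrix for the compiled integrator, one row per cell
params_matrix <- function(params) {
  stopifnot(is.list(params), length(params) >= 1L)
  m <- do.call(rbind, lapply(params, function(p) unlist(p[PAR_COLS])))
  colnames(m) <- PAR_COLS
  m
}
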