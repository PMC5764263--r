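## Connectivity masks over the fixed node set {PMC, SMA, M1, DLPFC}.
## Convention throughout: row = target, column = source.

#' Node labels of the motor-cognitive network
#' @export
roi_nodes <- function() c("PMC", "SMA", "M1", "DLPFC")

#' Intrinsic (A) connection mask
#'
#' All directed connections among the four nodes except DLPFC<->M1, which
#' are structurally excluded, and the diagonal, which is handled as a fixed
#' self-decay rather than a free parameter.
#' @return 4x4 binary matrix, row = target, column = source.
#' @export
a_mask_default <- function() {
  n <- roi_nodes()
  m <- matrix(1L, 4, 4, dimnames = list(n, n))
  diag(m) <- 0L
  m["M1", "DLPFC"] <- 0L
  m["DLPFC", "M1"] <- 0L
  m
}

## Structure catalogue for the modulatory (B) masks: six core modulations
## (PMC<->SMA, PMC<->M1, SMA<->M1) shared by every model, plus three binary
## toggles: modulation of DLPFC->PMC, of DLPFC->SMA, and the identity of a
## single return edge to DLPFC (from the family's input region or from the
## other secondary motor area). Structures 2 and 3 carry both DLPFC->
## modulations and differ only in the return edge, matching the published
## zero patterns for models 2/3 (PMC family) and 10/11 (SMA family).
structure_toggles <- function(structure) {
  tab <- list(
    c(pmc = 0L, sma = 0L, ret_input = 0L), # 1: core only + non-input return
    c(pmc = 1L, sma = 1L, ret_input = 0L), # 2
    c(pmc = 1L, sma = 1L, ret_input = 1L), # 3
    c(pmc = 0L, sma = 0L, ret_input = 1L), # 4
    c(pmc = 1L, sma = 0L, ret_input = 0L), # 5
    c(pmc = 1L, sma = 0L, ret_input = 1L), # 6
    c(pmc = 0L, sma = 1L, ret_input = 0L), # 7
    c(pmc = 0L, sma = 1L, ret_input = 1L)) # 8
  if (!is_count(structure) || structure < 1 || structure > 8)
    stop_config("structure must be an integer in 1..8")
  tab[[structure]]
}

#' Modulatory (B) connection mask for one model structure
#'
#' @param structure Integer 1..8 indexing the within-family structure.
#' @param input_region `"PMC"` or `"SMA"`; determines which return edge to
#'   DLPFC the `ret_input` toggle selects.
#' @return 4x4 binary matrix, row = target, column = source; DLPFC<->M1
#'   entries are always zero.
#' @export
b_mask_structure <- function(structure, input_region = c("PMC", "SMA")) {
  input_region <- match.arg(input_region)
  n <- roi_nodes()
  m <- matrix(0L, 4, 4, dimnames = list(n, n))
  core <- rbind(c("SMA", "PMC"), c("PMC", "SMA"),
                c("M1", "PMC"), c("PMC", "M1"),
                c("M1", "SMA"), c("SMA", "M1"))
  m[core] <- 1L
  tg <- structure_toggles(structure)
  if (tg[["pmc"]]) m["PMC", "DLPFC"] <- 1L
  if (tg[["sma"]]) m["SMA", "DLPFC"] <- 1L
  other <- if (input_region == "PMC") "SMA" else "PMC"
  ret_src <- if (tg[["ret_input"]]) input_region else other
  m["DLPFC", ret_src] <- 1L
  m
}

#' Driving-input (C) mask
#' @param input_region `"PMC"` or `"SMA"`.
#' @return Binary 4-vector with a single nonzero entry.
#' @export
c_mask_input <- function(input_region = c("PMC", "SMA")) {
  input_region <- match.arg(input_region)
  v <- setNames(integer(4), roi_nodes())
  v[input_region] <- 1L
  v
}
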