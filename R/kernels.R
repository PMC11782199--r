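# The twelve per-edge irregularity kernels.
#
# Every index here has the form  prefactor * sum over edges uv of h(d_u, d_v)
# with h symmetric and h(d, d) = 0, so each index vanishes exactly on regular
# graphs. Logarithms are natural throughout.

.irr_kernel_defs <- list(
  IRDIF = list(kernel = function(a, b) abs(a / b - b / a), prefactor = 1,
               label = "sum |du/dv - dv/du|"),
  AL    = list(kernel = function(a, b) abs(a - b), prefactor = 1,
               label = "Albertson: sum |du - dv|"),
  IRL   = list(kernel = function(a, b) abs(log(a) - log(b)), prefactor = 1,
               label = "sum |ln du - ln dv|"),
  IRLU  = list(kernel = function(a, b) abs(a - b) / pmin(a, b), prefactor = 1,
               label = "sum |du - dv| / min(du, dv)"),
  IRLF  = list(kernel = function(a, b) abs(a - b) / sqrt(a * b), prefactor = 1,
               label = "sum |du - dv| / sqrt(du dv)"),
  IRF   = list(kernel = function(a, b) (a - b)^2, prefactor = 1,
               label = "sum (du - dv)^2"),
  IRLA  = list(kernel = function(a, b) abs(a - b) / (a + b), prefactor = 2,
               label = "2 sum |du - dv| / (du + dv)"),
  IRD1  = list(kernel = function(a, b) log(1 + abs(a - b)), prefactor = 1,
               label = "sum ln(1 + |du - dv|)"),
  IRA   = list(kernel = function(a, b) (a^(-0.5) - b^(-0.5))^2, prefactor = 1,
               label = "sum (du^-1/2 - dv^-1/2)^2"),
  IRGA  = list(kernel = function(a, b) log((a + b) / (2 * sqrt(a * b))), prefactor = 2,
               label = "2 sum ln((du + dv) / 2 sqrt(du dv))"),
  IRB   = list(kernel = function(a, b) (sqrt(a) - sqrt(b))^2, prefactor = 1,
               label = "sum (sqrt(du) - sqrt(dv))^2"),
  IRRt  = list(kernel = function(a, b) abs(a - b), prefactor = 0.5,
               label = "total irregularity: 1/2 sum |du - dv|")
)

#' Identifiers of the twelve irregularity indices
#'
#' @return Character vector of the twelve index identifiers, in canonical
#'   order: IRDIF, AL, IRL, IRLU, IRLF, IRF, IRLA, IRD1, IRA, IRGA, IRB,
#'   IRRt.
#' @seealso [irr_kernels()] for the per-edge kernels behind each identifier.
#' @export
#' @examples
#' irr_indices()
irr_indices <- function() names(.irr_kernel_defs)

#' Per-edge kernel definitions of the irregularity indices
#'
#' Each irregularity index is a sum over the edges uv of a symmetric kernel
#' h(du, dv) of the endpoint degrees, times a constant prefactor. The kernel
#' vanishes on the diagonal (h(d, d) = 0), which is what makes every index an
#' irregularity measure: it is zero precisely on regular graphs.
#'
#' @param indices Character vector of index identifiers (see
#'   [irr_indices()]), or `"all"`.
#' @return Named list; each element has components `kernel` (vectorised
#'   function of two degree vectors), `prefactor` (numeric scalar) and
#'   `label` (human-readable definition).
#' @export
#' @examples
#' ks <- irr_kernels("IRF")
#' ks$IRF$kernel(4, 8)   # 16
irr_kernels <- function(indices = "all") {
  .irr_kernel_defs[resolve_indices(indices)]
}

# Validate and expand an index selection.
resolve_indices <- function(indices) {
  if (identical(indices, "all")) return(irr_indices())
  indices <- as.character(indices)
  bad <- setdiff(indices, irr_indices())
  if (length(bad) > 0L) {
    stop("unknown index identifier(s): ", paste(bad, collapse = ", "),
         "; see irr_indices()", call. = FALSE)
  }
  indices
}

# Evaluate prefactor * sum(count * kernel(d1, d2)) for one index over degree
# pairs; shared by the graph and partition computation paths.
kernel_sum <- function(id, d1, d2, count = 1) {
  if (any(d1 < 1) || any(d2 < 1)) {
    stop("index ", id, " is undefined for degree-0 endpoints", call. = FALSE)
  }
  def <- .irr_kernel_defs[[id]]
  def$prefactor * sum(count * def$kernel(d1, d2))
}
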