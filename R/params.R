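#' Default neuron-specific parameters
#'
#' Per-type conductance-based LIF parameters of the cerebellar microcircuit
#' model: membrane capacitance \code{C_m} (pF), leak conductance \code{g_L}
#' (nS), resting potential \code{E_L} (mV), refractory period \code{t_ref}
#' (ms), endogenous current \code{I_e} (pA), reset potential \code{V_r} (mV),
#' firing threshold \code{V_th} (mV), and the excitatory/inhibitory synaptic
#' decay time constants \code{tau_exc}, \code{tau_inh} (ms). Mossy fibers
#' (MF) and the inferior olive (IO) are Poisson spike sources, not LIF
#' units, so they carry no row here.
#'
#' @return A tibble with one row per LIF cell type
#'   (GrC, GoC, BC, SC, PC, DCN).
#' @export
#' @examples
#' lif_params()
lif_params <- function() {
  tibble::tibble(
    cell_type = c("GrC", "GoC", "BC", "SC", "PC", "DCN"),
    C_m     = c(3,    76,   14.6, 14.6, 620,  89),
    g_L     = c(1.5,  3.6,  1.0,  1.0,  7.0,  1.56),
    E_L     = c(-74,  -65,  -68,  -68,  -62,  -59),
    t_ref   = c(1.5,  2,    1.6,  1.6,  0.8,  3.7),
    I_e     = c(0,    36.8, 15.6, 15.6, 600,  55.8),
    V_r     = c(-84,  -75,  -78,  -78,  -72,  -69),
    V_th    = c(-42,  -55,  -53,  -53,  -47,  -48),
    tau_exc = c(0.5,  0.5,  0.64, 0.64, 0.5,  7.1),
    tau_inh = c(10,   15,   2,    2,    1.6,  13.6)
  )
}

#' Reference cell counts per population
#'
#' Population sizes at the reference 400 x 400 um footprint. Counts scale
#' linearly with footprint area. The single IO cell is a pure spike source
#' with no spatial position and does not scale.
#'
#' @return Named integer vector in canonical type order
#'   (MF, GrC, GoC, PC, SC, BC, DCN, IO).
#' @export
reference_counts <- function() {
  c(MF = 7070L, GrC = 88158L, GoC = 219L, PC = 69L,
    SC = 603L, BC = 603L, DCN = 12L, IO = 1L)
}

#' Canonical cell-type ordering
#'
#' Global neuron ids are assigned in contiguous blocks in this order.
#' @return Character vector of type names.
#' @export
cell_type_order <- function() {
  c("MF", "GrC", "GoC", "PC", "SC", "BC", "DCN", "IO")
}

#' Synaptic reversal potentials
#'
#' Shared across connection types: excitatory (AMPA-like) and inhibitory
#' (GABA-A-like) reversal potentials in mV. These values are standard for
#' the model lineage and are configurable.
#'
#' @return Named numeric vector with elements \code{E_exc}, \code{E_inh}.
#' @export
reversal_potentials <- function() {
  c(E_exc = 0, E_inh = -80)
}

#' Reference mean in-degrees per connection rule
#'
#' Expected convergence of each projection at the reference 400 x 400 um
#' footprint. Used by miniature fixtures to preserve the aggregate synaptic
#' conductance per target cell: when down-scaling shrinks a convergence,
#' the rule's weight is scaled up by the ratio of reference to realized
#' in-degree (standard network down-scaling practice).
#'
#' @return Named numeric vector, one entry per rule.
#' @export
reference_indegrees <- function() {
  c("MF-GrC" = 4, "MF-GoC" = 35, "GoC-GrC" = 4, "GoC-GoC" = 10,
    "AA-GoC" = 20, "PF-GoC" = 400, "SC-SC" = 4, "BC-BC" = 4,
    "PF-SC" = 300, "PF-BC" = 300, "SC-PC" = 22, "BC-PC" = 22,
    "AA-PC" = 3, "PF-PC" = 29196, "PC-DCN" = 69, "MF-DCN" = 4500)
}

# Calibrated sagittal half-width (um) of the parallel-fiber beam contacting
# a Purkinje cell. Solves (2h - h^2/L)/L * N_GrC = 29196 at the reference
# footprint (L = 400 um), i.e. mean band coverage for uniformly placed cells
# including edge truncation.
pf_band_halfwidth_default <- function() 72.87

#' Default connection rules
#'
#' The 16 connection types of the cerebellar microcircuit with their synaptic
#' weights (nS) and delays (ms), plus the geometric rule used to realize each
#' projection. Weights and delays are the model's published values; the
#' convergence geometry (radii, in-degrees, band half-widths) is anatomical
#' calibration, with the parallel fiber to Purkinje cell in-degree anchored
#' at 29,196 synapses per cell at the reference footprint.
#'
#' Geometry kinds:
#' \describe{
#'   \item{fixed_indegree}{each postsynaptic cell draws exactly \code{k}
#'     distinct presynaptic partners uniformly among those within
#'     \code{radius} um (planar distance); \code{radius = Inf} means any.}
#'   \item{sagittal_band}{connect iff |y_pre - y_post| <= \code{halfwidth}
#'     um (parallel fibers run the full transversal extent).}
#'   \item{cylinder}{connect iff planar (x, y) distance <= \code{radius} um
#'     (ascending axons rise vertically); if \code{k} is finite, a fixed
#'     in-degree is drawn among cells inside the cylinder.}
#'   \item{all_to_all}{every presynaptic cell contacts every postsynaptic
#'     cell.}
#' }
#'
#' @return A tibble with one row per connection rule.
#' @export
#' @examples
#' connection_rules()
connection_rules <- function() {
  h <- pf_band_halfwidth_default()
  tibble::tribble(
    ~name,      ~pre,  ~post, ~sign,  ~weight, ~delay, ~geometry,        ~k,   ~radius,
    "MF-GrC",   "MF",  "GrC", "exc",  9.0,     4,      "fixed_indegree", 4,    60,
    "MF-GoC",   "MF",  "GoC", "exc",  2.0,     4,      "fixed_indegree", 35,   150,
    "GoC-GrC",  "GoC", "GrC", "inh",  5.0,     2,      "fixed_indegree", 4,    100,
    "GoC-GoC",  "GoC", "GoC", "inh",  8.0,     1,      "fixed_indegree", 10,   150,
    "AA-GoC",   "GrC", "GoC", "exc",  20.0,    2,      "cylinder",       20,   30,
    "PF-GoC",   "GrC", "GoC", "exc",  0.4,     5,      "band_indegree",  400,  h,
    "SC-SC",    "SC",  "SC",  "inh",  2.0,     1,      "fixed_indegree", 4,    100,
    "BC-BC",    "BC",  "BC",  "inh",  2.5,     1,      "fixed_indegree", 4,    100,
    "PF-SC",    "GrC", "SC",  "exc",  0.2,     5,      "band_indegree",  300,  h,
    "PF-BC",    "GrC", "BC",  "exc",  0.2,     5,      "band_indegree",  300,  h,
    "SC-PC",    "SC",  "PC",  "inh",  8.5,     5,      "sagittal_fixed", 22,   100,
    "BC-PC",    "BC",  "PC",  "inh",  9.0,     4,      "sagittal_fixed", 22,   100,
    "AA-PC",    "GrC", "PC",  "exc",  75.0,    2,      "cylinder",       3,    30,
    "PF-PC",    "GrC", "PC",  "exc",  0.02,    5,      "sagittal_band",  NA,   h,
    "PC-DCN",   "PC",  "DCN", "inh",  0.0075,  4,      "all_to_all",     NA,   NA,
    "MF-DCN",   "MF",  "DCN", "exc",  0.006,   4,      "fixed_indegree", 4500, Inf
  )
}
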