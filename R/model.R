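#' Full model configuration
#'
#' Collects every tunable of the scaffold in one nested list: volume and
#' layer geometry, per-type cell counts at the reference footprint, LIF
#' parameters, reversal potentials, connection rules, engine resolution,
#' and plasticity constants. Every field is overridable; the defaults are
#' the published model.
#'
#' @param volume A [volume_spec()].
#' @param counts Named reference counts, default [reference_counts()].
#' @param lif Per-type LIF tibble, default [lif_params()].
#' @param reversal Default [reversal_potentials()].
#' @param rules Connection rule tibble, default [connection_rules()].
#' @param engine List with \code{dt_substep} (0.1 ms), \code{dt_exchange}
#'   (1 ms), \code{flush_interval} (50 ms).
#' @param plasticity A [plasticity_params()].
#' @return A \code{model_config} list.
#' @export
model_config <- function(volume = volume_spec(),
                         counts = reference_counts(),
                         lif = lif_params(),
                         reversal = reversal_potentials(),
                         rules = connection_rules(),
                         engine = list(dt_substep = 0.1, dt_exchange = 1,
                                       flush_interval = 50),
                         plasticity = plasticity_params()) {
  stopifnot(engine$dt_exchange %% engine$dt_substep < 1e-9 ||
              abs(engine$dt_exchange / engine$dt_substep -
                    round(engine$dt_exchange / engine$dt_substep)) < 1e-9)
  if (any(rules$delay < engine$dt_exchange)) {
    stop("all synaptic delays must be >= the exchange interval", call. = FALSE)
  }
  structure(list(volume = volume, counts = counts, lif = lif,
                 reversal = reversal, rules = rules, engine = engine,
                 plasticity = plasticity),
            class = "model_config")
}

#' Build a complete model
#'
#' Places the populations, realizes the connectome, and assembles the
#' runnable network.
#'
#' @param config A [model_config()].
#' @param seed Integer seed (placement and connectivity).
#' @param scale Count scale factor (fixtures use < 1).
#' @param relax_indegree Passed to [build_connectivity()].
#' @return A \code{cereb_model} list: \code{placement}, \code{store},
#'   \code{network}, \code{config}, \code{seed}.
#' @export
build_model <- function(config = model_config(), seed = 1, scale = 1,
                        relax_indegree = scale < 1) {
  pops <- population_spec(config$volume, config$counts, scale = scale)
  pl <- place_populations(config$volume, pops, seed = seed)
  store <- build_connectivity(pl, config$rules, seed = counter_mix(seed, 11L, 0L),
                              relax_indegree = relax_indegree)
  net <- build_network(pl, store, lif = config$lif, reversal = config$reversal)
  structure(list(placement = pl, store = store, network = net,
                 config = config, seed = seed, scale = scale),
            class = "cereb_model")
}

#' @export
print.cereb_model <- function(x, ...) {
  cat(sprintf("<cereb_model> scale %g, %d cells, %d connection rules\n",
              x$scale, nrow(x$placement), length(x$store)))
  invisible(x)
}

#' Miniature test fixture
#'
#' A statistically faithful scaled-down scaffold: counts scale by
#' \code{scale}, the footprint area by the same factor (extents by
#' \code{sqrt(scale)}), so layer densities match the reference model. All
#' connection rules are retained; fixed in-degrees larger than a miniature
#' population are truncated with a warning.
#'
#' By default the miniature preserves each target cell's aggregate synaptic
#' drive: for every rule whose realized mean convergence falls below its
#' reference value ([reference_indegrees()]), the synaptic weight is scaled
#' up by the reference-to-realized in-degree ratio. Without this the
#' operating points of the sparse projections (notably parallel
#' fiber-Purkinje) collapse at small scales.
#'
#' @param scale Count scale factor, e.g. 0.01 for a ~900-cell scaffold.
#' @param seed Integer seed.
#' @param config Base configuration (reference defaults).
#' @param compensate_weights Preserve aggregate conductance (default TRUE).
#' @return A \code{cereb_model}.
#' @export
#' @examples
#' \donttest{
#' fx <- scaffold_fixture(0.01, seed = 1)
#' }
scaffold_fixture <- function(scale = 0.01, seed = 1,
                             config = model_config(),
                             compensate_weights = TRUE) {
  stopifnot(scale > 0)
  v <- config$volume
  config$volume <- volume_spec(
    x_extent = v$x_extent * sqrt(scale),
    y_extent = v$y_extent * sqrt(scale),
    z_extent = v$z_extent, layers = v$layers
  )
  # counts scale with footprint area; neutralize so `scale` acts once
  m <- build_model(config, seed = seed, scale = 1, relax_indegree = TRUE)
  if (compensate_weights && scale < 1) {
    ref_k <- reference_indegrees()
    for (nm in names(m$store)) {
      r <- m$store[[nm]]
      indeg <- diff(r$csr$p)
      k_fix <- if (length(indeg)) mean(indeg) else 0
      k_ref <- ref_k[[nm]]
      if (!is.null(k_ref) && k_fix > 0 && k_fix < k_ref) {
        m$store[[nm]]$weight <- r$weight * k_ref / k_fix
      }
    }
    m$network <- build_network(m$placement, m$store, lif = config$lif,
                               reversal = config$reversal)
  }
  m
}

config_to_list <- function(cfg) {
  list(
    volume = list(x_extent = cfg$volume$x_extent,
                  y_extent = cfg$volume$y_extent,
                  z_extent = cfg$volume$z_extent,
                  layers = lapply(cfg$volume$layers, as.numeric)),
    counts = as.list(cfg$counts),
    lif = as.list(cfg$lif),
    reversal = as.list(cfg$reversal),
    rules = as.list(cfg$rules),
    engine = cfg$engine,
    plasticity = unclass(cfg$plasticity)
  )
}

config_from_list <- function(lst) {
  def <- config_to_list(model_config())
  unknown <- setdiff(names(lst), names(def))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(lst)) {
    sub <- lst[[sec]]
    if (is.list(sub) && is.list(def[[sec]])) {
      bad <- setdiff(names(sub), names(def[[sec]]))
      if (length(bad)) {
        stop(sprintf("unknown key(s) in %s: %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      def[[sec]][names(sub)] <- sub
    } else if (!is.null(sub)) {
      def[[sec]] <- sub
    }
  }
  flat <- function(x) lapply(x, function(col) {
    if (is.list(col)) unlist(col) else col
  })
  model_config(
    volume = volume_spec(def$volume$x_extent, def$volume$y_extent,
                         def$volume$z_extent,
                         layers = flat(def$volume$layers)),
    counts = unlist(def$counts),
    lif = tibble::as_tibble(flat(def$lif)),
    reversal = unlist(def$reversal),
    rules = tibble::as_tibble(flat(def$rules)),
    engine = flat(def$engine),
    plasticity = do.call(plasticity_params, flat(def$plasticity))
  )
}

#' Load / write a model configuration (YAML)
#'
#' An empty or missing-section file yields the full default configuration;
#' unknown keys are rejected with the offending name. Write-then-read
#' round-trips to an identical configuration.
#'
#' @param path YAML file path.
#' @return \code{load_config} returns a [model_config()];
#'   \code{write_config} returns \code{path} invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  if (is.null(lst)) lst <- list()
  config_from_list(lst)
}

#' @rdname load_config
#' @param config A [model_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
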