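#' Build a fixed in-degree bipartite topology
#'
#' Constructs a directed source-to-receiver connection graph in which every
#' receiver draws exactly `k` distinct source neurons uniformly at random,
#' independently of the other receivers. Fixed in-degree is the defining
#' constraint of the common-drive model: the expected input overlap between
#' two receivers is then `k^2 / n_source` shared sources, i.e. a shared-input
#' fraction of `k / n_source`.
#'
#' @param n_source Number of source (presynaptic) neurons.
#' @param n_receiver Number of receiver (postsynaptic) neurons.
#' @param k In-degree: connections per receiver. Must satisfy
#'   `1 <= k <= n_source` (`k <= n_source - 1` when `exclude_self = TRUE`).
#' @param seed Optional integer seed for reproducible wiring.
#' @param sign Edge sign, `+1` (excitatory) or `-1` (inhibitory).
#' @param exclude_self If `TRUE`, treat source and receiver as the same
#'   population and forbid self-connections (used for recurrent graphs).
#' @param source_pop,target_pop Population labels carried into the edge list.
#'
#' @return A `cpg_topology`: a tibble with columns `source`, `target`, `sign`
#'   (1-based indices within each population) and attributes `n_source`,
#'   `n_receiver`, `in_degree`.
#' @examples
#' top <- build_fixed_indegree(20, 30, k = 10, seed = 1)
#' glance(top)
#' @export
build_fixed_indegree <- function(n_source, n_receiver, k, seed = NULL,
                                 sign = 1L, exclude_self = FALSE,
                                 source_pop = "source",
                                 target_pop = "receiver") {
  n_source <- check_count(n_source, "n_source")
  n_receiver <- check_count(n_receiver, "n_receiver")
  k <- check_count(k, "k")
  k_max <- if (exclude_self) n_source - 1L else n_source
  if (k > k_max) {
    abort(sprintf("In-degree k = %d exceeds the available sources (%d).", k, k_max))
  }
  set_seed_if(seed)
  sources <- vapply(seq_len(n_receiver), function(r) {
    pool <- if (exclude_self) setdiff(seq_len(n_source), r) else seq_len(n_source)
    sample(pool, k, replace = FALSE)
  }, integer(k))
  edges <- tibble(
    source = as.integer(sources),
    target = rep(seq_len(n_receiver), each = k),
    sign = as.integer(sign)
  )
  new_cpg_topology(edges, n_source, n_receiver, k, source_pop, target_pop)
}

new_cpg_topology <- function(edges, n_source, n_receiver, in_degree,
                             source_pop = "source", target_pop = "receiver") {
  structure(
    edges,
    n_source = n_source,
    n_receiver = n_receiver,
    in_degree = in_degree,
    source_pop = source_pop,
    target_pop = target_pop,
    class = c("cpg_topology", class(tibble())))
}

#' Sparseness of a fixed in-degree topology
#'
#' Sparseness is the complement of graph density for a bipartite projection
#' with constant in-degree: `rho = 1 - C / C_max = 1 - k / n_source`, where
#' `C = k * n_receiver` edges exist out of `C_max = n_source * n_receiver`
#' possible ones. A value near 1 means each receiver samples only a small
#' fraction of the source population.
#'
#' @param topology A `cpg_topology`, or an in-degree `k` when `n_source` is
#'   also given.
#' @param n_source Source population size (only when `topology` is numeric).
#' @return Sparseness in `[0, 1)`.
#' @examples
#' sparseness(10, 20)   # 0.5
#' sparseness(10, 500)  # 0.98
#' @export
sparseness <- function(topology, n_source = NULL) {
  if (inherits(topology, "cpg_topology")) {
    k <- attr(topology, "in_degree")
    n <- attr(topology, "n_source")
  } else {
    k <- check_count(topology, "k")
    n <- check_count(n_source, "n_source")
  }
  1 - k / n
}

#' Predicted fast-timescale correlation from shared input
#'
#' For two receivers that each draw `k` of `n_source` inputs uniformly, the
#' expected number of shared sources is `k^2 / n_source`, so the expected
#' shared-input fraction -- and hence the predicted fast-timescale Pearson
#' correlation of their synaptic input -- is `k / n_source`.
#'
#' @param k In-degree per receiver.
#' @param n_source Source population size.
#' @return Predicted correlation in `(0, 1]`.
#' @examples
#' predicted_correlation(10, 20)   # 0.5
#' predicted_correlation(10, 500)  # 0.02
#' @export
predicted_correlation <- function(k, n_source) {
  k <- check_count(k, "k")
  n_source <- check_count(n_source, "n_source")
  if (k > n_source) abort(sprintf("In-degree k = %d exceeds n_source = %d.", k, n_source))
  k / n_source
}

#' Specify a connectivity motif
#'
#' The three input scenarios used to study active decorrelation:
#' `ff_exc` is pure feedforward excitation from the drive population onto the
#' receivers; `ff_inh` adds a feedforward inhibitory population (drive ->
#' inhibitory -> receivers); `recurrent_inh` additionally connects the
#' inhibitory population to itself. Sparseness values are converted to
#' integer in-degrees by `k = max(1, round((1 - rho) * n))`.
#'
#' @param motif One of `"ff_exc"`, `"ff_inh"`, `"recurrent_inh"`.
#' @param rho_drive Sparseness of the drive projections (drive -> receiver
#'   and drive -> inhibitory).
#' @param rho_inh Sparseness of the inhibitory -> receiver projection.
#' @param rho_rec Sparseness of the recurrent inhibitory -> inhibitory graph.
#' @param n_source,n_inh,n_receiver Population sizes. The drive population
#'   size is a configuration value (the motif studies fix only its
#'   sparseness); the default of 100 matches the inhibitory and receiver
#'   population sizes.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(motif = c("ff_exc", "ff_inh", "recurrent_inh"),
                       rho_drive = 0.5, rho_inh = 0.9, rho_rec = 0.9,
                       n_source = 100, n_inh = 100, n_receiver = 100) {
  motif <- match.arg(motif)
  for (nm in c("rho_drive", "rho_inh", "rho_rec")) {
    val <- get(nm)
    check_scalar_number(val, nm, min = 0)
    if (val >= 1) abort(sprintf("`%s` must be < 1 (got %s): sparseness 1 leaves no connections.", nm, val))
  }
  structure(
    list(motif = motif, rho_drive = rho_drive, rho_inh = rho_inh,
         rho_rec = rho_rec,
         n_source = check_count(n_source, "n_source"),
         n_inh = check_count(n_inh, "n_inh"),
         n_receiver = check_count(n_receiver, "n_receiver")),
    class = "motif_spec")
}

rho_to_k <- function(rho, n) max(1L, as.integer(round((1 - rho) * n)))

#' Build the connection graphs of a motif
#'
#' Expands a [motif_spec()] into its constituent fixed in-degree graphs.
#' Self-connections are excluded in the recurrent inhibitory graph.
#'
#' @param spec A [motif_spec()].
#' @param seed Integer seed; sub-graphs get deterministic derived seeds.
#' @return A `cpg_motif`: named list of `cpg_topology` objects among
#'   `drive_receiver`, `drive_inh`, `inh_receiver`, `inh_inh`, with the spec
#'   attached.
#' @examples
#' m <- build_motif(motif_spec("recurrent_inh"), seed = 1)
#' names(m)
#' @export
build_motif <- function(spec, seed = NULL) {
  if (!inherits(spec, "motif_spec")) abort("`spec` must be a motif_spec.")
  graphs <- list(
    drive_receiver = build_fixed_indegree(
      spec$n_source, spec$n_receiver, rho_to_k(spec$rho_drive, spec$n_source),
      seed = if (is.null(seed)) NULL else derive_seed(seed, 1L),
      sign = 1L, source_pop = "drive", target_pop = "receiver"))
  if (spec$motif %in% c("ff_inh", "recurrent_inh")) {
    graphs$drive_inh <- build_fixed_indegree(
      spec$n_source, spec$n_inh, rho_to_k(spec$rho_drive, spec$n_source),
      seed = if (is.null(seed)) NULL else derive_seed(seed, 2L),
      sign = 1L, source_pop = "drive", target_pop = "inh")
    graphs$inh_receiver <- build_fixed_indegree(
      spec$n_inh, spec$n_receiver, rho_to_k(spec$rho_inh, spec$n_inh),
      seed = if (is.null(seed)) NULL else derive_seed(seed, 3L),
      sign = -1L, source_pop = "inh", target_pop = "receiver")
  }
  if (spec$motif == "recurrent_inh") {
    graphs$inh_inh <- build_fixed_indegree(
      spec$n_inh, spec$n_inh, rho_to_k(spec$rho_rec, spec$n_inh),
      seed = if (is.null(seed)) NULL else derive_seed(seed, 4L),
      sign = -1L, exclude_self = TRUE, source_pop = "inh", target_pop = "inh")
  }
  structure(graphs, spec = spec, class = "cpg_motif")
}

#' @export
print.cpg_topology <- function(x, ...) {
  cat(sprintf("<cpg_topology> %s -> %s: n_source = %d, n_receiver = %d, k = %d, rho = %.3f\n",
              attr(x, "source_pop"), attr(x, "target_pop"),
              attr(x, "n_source"), attr(x, "n_receiver"),
              attr(x, "in_degree"), sparseness(x)))
  NextMethod()
}

#' @rdname build_fixed_indegree
#' @param x A `cpg_topology`.
#' @param ... Unused.
#' @export
tidy.cpg_topology <- function(x, ...) {
  tibble(source = x$source, target = x$target, sign = x$sign)
}

#' @rdname build_fixed_indegree
#' @export
glance.cpg_topology <- function(x, ...) {
  tibble(
    n_source = attr(x, "n_source"),
    n_receiver = attr(x, "n_receiver"),
    in_degree = attr(x, "in_degree"),
    n_edges = nrow(x),
    sparseness = sparseness(x),
    predicted_correlation = attr(x, "in_degree") / attr(x, "n_source"))
}

#' Write / read a topology edge list
#'
#' Plain tab-separated edge list with a commented header carrying the
#' population names and sizes; indices are 1-based.
#'
#' @param x A `cpg_topology`.
#' @param path File path.
#' @return `read_topology()` returns a `cpg_topology`.
#' @export
write_topology <- function(x, path) {
  header <- sprintf(
    "# cpg_topology\n# source_pop: %s\n# target_pop: %s\n# n_source: %d\n# n_receiver: %d\n# in_degree: %d",
    attr(x, "source_pop"), attr(x, "target_pop"),
    attr(x, "n_source"), attr(x, "n_receiver"), attr(x, "in_degree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(paste0("^# ", name, ":"), hdr, value = TRUE)
    if (!length(m)) abort(sprintf("Malformed topology file: missing header field '%s'.", name))
    sub(paste0("^# ", name, ":\\s*"), "", m[1])
  }
  edges <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                             sep = "\t")
  new_cpg_topology(
    tibble(source = as.integer(edges$source), target = as.integer(edges$target),
           sign = as.integer(edges$sign)),
    n_source = as.integer(get_field("n_source")),
    n_receiver = as.integer(get_field("n_receiver")),
    in_degree = as.integer(get_field("in_degree")),
    source_pop = get_field("source_pop"),
    target_pop = get_field("target_pop"))
}
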