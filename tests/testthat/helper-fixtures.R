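# Shared fixtures, memoized across test files (helpers are sourced once per
# test session, so expensive geometry is built at most once).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_phantom <- function() {
  cached("phantom", generate_synthetic_phantom(synthetic_spec()))
}

default_schedule <- function() {
  cached("schedule", solve_rk4(build_model()))
}

liver_mesh_smoothed <- function() {
  cached("liver_smooth", laplacian_smooth(extract_surface(default_phantom(),
                                                          "liver")))
}

liver_shell <- function() {
  cached("liver_shell", extrude_shell(liver_mesh_smoothed(), 2))
}

# tiny phantom: a 7x7x7 block of `body` containing a 3x3x3 core of `organ`
toy_phantom <- function() {
  lab <- array(0L, c(9, 9, 9))
  lab[2:8, 2:8, 2:8] <- 1L
  lab[4:6, 4:6, 4:6] <- 2L
  load_voxel_phantom(lab, 1, data.frame(
    id = 1:2, name = c("body", "organ"),
    role = c("body", "other"), stringsAsFactors = FALSE))
}

# single-washout model: one compartment draining to excreted at rate k
washout_model <- function(k, A0 = 1) {
  build_model(list(
    compartments = c("central", "excreted"),
    rates = data.frame(from = "central", to = "excreted", rate = k,
                       stringsAsFactors = FALSE),
    A0_MBq = A0))
}

# independent connected-component count via igraph (test oracle)
igraph_component_count <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  co <- arrayInd(idx, d)
  id_of <- array(0L, d)
  id_of[idx] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    sh <- co
    sh[, ax] <- sh[, ax] + 1L
    ok <- sh[, ax] <= d[ax]
    nb <- id_of[sh[ok, , drop = FALSE]]
    has <- nb > 0L
    edges <- rbind(edges, cbind(which(ok)[has], nb[has]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}
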