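# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small phantom: 60 x 60 x 40 tank, 2 x 2 electrode array (~4k tets)
small_tank <- function() tank_spec(60, 60, 40, target_edge_mm = 9)
small_layout <- function() {
  electrode_layout(small_tank(), n_rows = 2, n_cols = 2, radius_mm = 2,
                   gap_mm = 8, back_radius_mm = 6)
}
small_mesh <- function() {
  cached("small_mesh", function() build_tank_mesh(small_tank(), small_layout()))
}

# even smaller phantom for conditioning diagnostics (~4k elements, 12 meas)
cond_layout_tank <- function() tank_spec(36, 36, 24, target_edge_mm = 5.5)
cond_jacobian <- function() {
  cached("cond_jacobian", function() {
    tk <- cond_layout_tank()
    ly <- electrode_layout(tk, n_rows = 2, n_cols = 2, radius_mm = 2,
                           gap_mm = 8, back_radius_mm = 4)
    m <- build_tank_mesh(tk, ly)
    list(mesh = m, layout = ly,
         J = compute_jacobian(m, make_conductivity_field(m, 0.1), ly))
  })
}

# structured box without electrodes for analytic field tests
box_mesh <- function(L = 80, h = 5) {
  cached(sprintf("box_%g_%g", L, h), function() {
    build_tank_mesh(tank_spec(L, L, L, target_edge_mm = h))
  })
}

# analytic node field wrapper
node_field <- function(mesh, values) {
  structure(list(f = values, grad = NULL, lap = NULL, n_nodes = mesh$n_nodes),
            class = "node_scalar_field")
}

# differentiated field whose Laplacian is replaced by a prescribed function
# (exercises the marching-tetrahedra extraction against exact geometry)
field_with_lap <- function(mesh, f_vals, lap_vals) {
  fld <- differentiate(node_field(mesh, f_vals), mesh)
  fld$lap <- lap_vals
  fld
}

edge_set_all <- function(mesh) {
  me <- planareit:::mesh_edges(mesh)
  structure(list(element_ids = seq_len(mesh$n_elements),
                 n_intersected = rep(6L, mesh$n_elements),
                 edge_intersected = rep(TRUE, nrow(me$edges)),
                 edges = me$edges, elem_edges = me$elem_edges,
                 component_labels = rep(1L, mesh$n_elements)),
            class = "edge_element_set")
}

surface_components <- function(surface) {
  if (nrow(surface$triangles) == 0) return(0L)
  g <- igraph::graph_from_edgelist(
    rbind(surface$triangles[, c(1, 2)], surface$triangles[, c(2, 3)]),
    directed = FALSE)
  as.integer(igraph::components(g)$no)
}
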