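# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

shared_head <- function() fixture("head", function() make_head(seed = 1))

shared_layout <- function() fixture("layout", function()
  standard_layout_68(shared_head()))

shared_painted <- function() fixture("painted", function()
  paint_electrodes(shared_head(), shared_layout()))

shared_canonical <- function() fixture("canonical", function()
  standard_layout_68())

shared_templates <- function() fixture("templates", function()
  default_templates())

shared_detected <- function() fixture("detected", function()
  detect_electrodes(shared_painted()$mesh))

# a deterministic small textured sphere with one painted disc facing +z
disc_sphere <- function(disc_dir = c(0, 0, 1), radius = 50, disc_mm = 6) {
  fixture(paste0("disc_sphere_", paste(disc_dir, collapse = "_")), function() {
    ico <- headgeo:::icosphere(4)
    u <- ico$vertices
    uv_vert <- headgeo:::sphere_uv(u)
    uv <- uv_vert[t(ico$faces), , drop = FALSE]
    for (f in seq_len(nrow(ico$faces))) {
      idx <- (f - 1L) * 3L + 1:3
      uu <- uv[idx, 1]
      if (max(uu) - min(uu) > 0.5) uv[idx, 1] <- ifelse(uu < 0.5, uu + 1, uu)
    }
    mesh <- textured_mesh(u * radius, ico$faces, uv = uv)
    center <- disc_dir / sqrt(sum(disc_dir^2)) * radius
    pe <- paint_electrodes(mesh, electrode_set(matrix(center, 1, 3)),
                           radius_mm = disc_mm, texture_size = c(512, 1024))
    list(mesh = pe$mesh, center = pe$centers$points[1, ])
  })
}

# draw a filled disc in a binary raster (row/col convention as the package)
raster_disc <- function(H, W, cx, cy, r) {
  img <- matrix(0, H, W)
  for (rr in seq_len(H))
    for (cc in seq_len(W))
      if ((cc - 0.5 - cx)^2 + (rr - 0.5 - cy)^2 <= r^2) img[rr, cc] <- 1
  img
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
}
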