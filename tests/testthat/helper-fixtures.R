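# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code (no stored data) under fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a mean-parameter atrium shape + its default-grid volume (coarse mesh)
fixtureShape <- function() fixture("shape", function() {
  buildAtrium(defaultShapeModel()@mean, meshRes = 2, id = "fixture")
})

fixtureVolume <- function() fixture("volume", function() {
  voxelizeShape(fixtureShape(), GridSpec())
})

# small seeded dataset on the scaled-down 24^3 grid
fixtureDataset <- function() fixture("dataset", function() {
  generateDataset(6, 2, defaultShapeModel(), GridSpec(24, 5), seed = 11,
                  meshRes = 2.5)
})

# sphere mesh of given radius via the package's own iso-surfacing of an
# analytic field (1 inside the ball), used as an analytic reference surface
sphereMesh <- function(radius, res = 1.5, center = c(0, 0, 0)) {
  n <- ceiling(2 * (radius + 3 * res) / res) + 1L
  ax <- seq(-(radius + 3 * res), radius + 3 * res, length.out = n)
  g <- expand.grid(x = ax, y = ax, z = ax)
  f <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 +
            (g$z - center[3])^2) - radius
  mm <- atriarecon:::.marchingTets(f, c(n, n, n), ax + center[1],
                                   ax + center[2], ax + center[3], 0)
  TriMesh(mm$vertices, mm$faces)
}

# toy 12^3 ellipsoid completion problem: sparse interior samples -> full
# ellipsoid (the scaled-down training benchmark for the networks)
toyEllipsoidPairs <- function(n = 50, seed = 100, grid = GridSpec(12, 5),
                              frac = 0.08) {
  withr::with_seed(seed, {
    ax <- voxelAxes(grid)
    g <- expand.grid(x = ax$x, y = ax$y, z = ax$z)
    lapply(seq_len(n), function(i) {
      ctr <- runif(3, -6, 6); sa <- runif(3, 14, 22)
      inside <- ((g$x - ctr[1]) / sa[1])^2 + ((g$y - ctr[2]) / sa[2])^2 +
        ((g$z - ctr[3]) / sa[3])^2 <= 1
      tgt <- OccupancyVolume(array(as.numeric(inside), grid@dims), grid)
      iv <- which(inside)
      pick <- sample(iv, max(3L, round(length(iv) * frac)))
      inp <- array(0, grid@dims); inp[pick] <- 1
      list(inp = OccupancyVolume(inp, grid), tgt = tgt)
    })
  })
}

# random small occupancy volume (arbitrary binary field, no connectivity
# guarantee) for graph/oracle tests
randomVolume <- function(dims, p = 0.7, seed = 1, spacing = 2) {
  withr::with_seed(seed, {
    v <- array(rbinom(prod(dims), 1L, p), dims)
    OccupancyVolume(v, GridSpec(dims, spacing))
  })
}

# independent Bellman-Ford oracle over an explicit edge list (undirected)
bellmanFordCost <- function(nNodes, edges, costs, src, dst) {
  dist <- rep(Inf, nNodes)
  dist[src] <- 0
  for (iter in seq_len(nNodes)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]; w <- costs[e]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist[dst]
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

subToLinearR <- function(dims, sub) {
  if (is.null(dim(sub))) sub <- matrix(sub, ncol = 3L)
  atriarecon:::subToLinear(as.integer(dims), sub)
}

fixtureDatasetVolume <- function(i) fixtureDataset()@samples[[i]]$volume
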