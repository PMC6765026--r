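# shared fixtures: kind list and (h,k) grids, built in code

all_kinds <- lattice_kinds()

hk_grid <- function(hmax) {
  out <- list()
  for (h in 1:hmax) for (k in 0:h) out[[length(out) + 1L]] <- c(h, k)
  out
}

# rotation matrix about axis u (unit) by angle theta (Rodrigues)
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# largest distance from each rotated vertex to its nearest original vertex
max_nn_dist <- function(a, b) {
  max(apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2)))))
}
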