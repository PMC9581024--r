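library(splatfit)
set.seed(1)
for (n in c(40, 350)) {
  A <- matrix(runif(3*n, -1, 1), n, 3)
  cat("n =", n, ":")
  for (deg in c(15, 25, 35, 45, 60)) {
    ok <- 0
    for (rep in 1:10) {
      ax <- rnorm(3); ax <- ax/sqrt(sum(ax^2))
      R <- axis_angle_to_matrix(ax * deg * pi/180)
      B <- A %*% t(R)
      res <- icp_align(A, B, max_iter = 200)
      if (res$rmsd < 1e-6) ok <- ok + 1
    }
    cat(sprintf(" %ddeg:%d/10", deg, ok))
  }
  cat("\n")
}
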