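# Independent Jones-calculus oracle for the Mueller element constructors.
# Convention anchored to S3 = +1 for right-circular light: coherency
# transform with A's circular row (0, i, -i, 0) and retarder Jones matrix
# diag(1, exp(i*delta)) at fast axis 0.

.A <- rbind(c(1, 0, 0, 1),
            c(1, 0, 0, -1),
            c(0, 1, 1, 0),
            c(0, 1i, -1i, 0))
.Ainv <- solve(.A)

jonesToMueller <- function(J) Re(.A %*% (J %x% Conj(J)) %*% .Ainv)

jonesRotation <- function(angleDeg) {
  t <- angleDeg * pi / 180
  rbind(c(cos(t), sin(t)), c(-sin(t), cos(t)))
}

jonesPolarizer <- function(axisDeg) {
  R <- jonesRotation(axisDeg)
  t(R) %*% diag(c(1, 0)) %*% R
}

jonesRetarder <- function(fastAxisDeg, retardance) {
  R <- jonesRotation(fastAxisDeg)
  t(R) %*% diag(c(1, exp(1i * retardance))) %*% R
}

# Uniformly random physical Stokes vectors: random total intensity, random
# DOP in [0, 1], random direction on the Poincare sphere.
randomPhysicalStokes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s0 <- runif(n, 0.1, 10)
  dop <- runif(n)
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  unname(cbind(s0, s0 * dop * r * cos(phi), s0 * dop * r * sin(phi),
               s0 * dop * z))
}

# Small standard phantom used across tests; cheap but populated.
smallPhantom <- function(seed = 11, nPerClass = 1, size = 72, ...) {
  phantomSpec(imageSize = size, nCellsPerClass = nPerClass,
              cellRadiusRange = c(6, 9), seed = seed, ...)
}
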