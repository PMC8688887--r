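# Precomputed 12- and 16-point sets whose even moments match the uniform
# sphere as closely as 12/16 points allow (frame-potential residuals
# 1.3e-7 and < 1e-14 through degree 6). They make the finite powder
# average a near-exact rotational average, which the powder cumulant fit
# relies on. Frozen constants so direction sets are identical everywhere.
.dirs12 <- matrix(c(
  0.79826629101425062, 0.18263588016549856, 0.5739469173246996,
  0.36488289417587655, 0.92637060048056785, 0.093262983563191779,
  0.88037056002296543, -0.11405248928357423, -0.4603690983689831,
  0.47644633668321934, -0.42907216148251198, 0.76739557498194211,
  0.50984616811118688, 0.46255703219434424, -0.72532604863599082,
  0.87857810915126466, -0.45249054660230092, 0.15281626665947382,
  0.877333968803782, 0.47693717475515002, -0.05306635958476736,
  0.42682314099075308, -0.54648588192077641, -0.72053812333287326,
  0.28581400397850126, 0.6320706315834802, 0.72027569153723203,
  -0.022897123563350941, 0.86150623082017241, -0.50723045648949794,
  -0.40066661385761593, 0.90815523290363798, 0.12132739793472509,
  0.031931986857216835, 0.0068931683239257732, -0.99946627379107122),
  ncol = 3, byrow = TRUE)

.dirs16 <- matrix(c(
  0.98589246267395925, 0.098402509775056948, 0.13539940218718002,
  -0.83800775789290582, 0.40565278713532721, 0.36495042677142592,
  0.33451344357962171, -0.78312026537531254, -0.52423602129480118,
  -0.45979321770783599, 0.23741400597571846, 0.85570134200925274,
  -0.86045546501910197, -0.24255121673613439, 0.44809072739634059,
  0.16415498813531645, -0.053428505695948043, 0.98498656572026,
  0.20926813911195036, 0.94938466455521608, 0.23425542610578157,
  -0.67660108441012401, -0.72790963920339791, 0.11116892429911948,
  -0.32554153067155472, 0.61270023046893995, -0.72015355264785652,
  0.39164668766756555, 0.37578148543171719, -0.839881626924745,
  -0.17996102718780529, -0.52714672251912642, -0.83050006720701297,
  0.79706978640261517, -0.57014444401312436, 0.19903534501453457,
  0.20266088122477266, 0.84379487691383914, -0.49692934398680638,
  0.67605267998625762, 0.52487959002640749, 0.51715973340652599,
  -0.33276778142636004, 0.93679006453972335, -0.10812020451441644,
  0.7288002104249538, -0.10906227686929236, 0.67598496510545913),
  ncol = 3, byrow = TRUE)

#' Deterministic well-spread gradient direction sets
#'
#' Returns `n` unit vectors spread over the sphere. Three sizes use
#' purpose-built sets: `n = 6` the classic icosahedral DTI scheme, and
#' `n = 12` / `n = 16` numerically optimized even-moment quadrature sets
#' (near projective 3-designs), so shell powder averages closely match the
#' rotational average. Other sizes use a Fibonacci (golden-angle) spiral.
#' All constructions are deterministic. Diffusion encoding is antipodally
#' symmetric, so no sign convention is imposed.
#'
#' @param n Number of directions (>= 1).
#' @return An `n x 3` matrix of unit row vectors.
#' @export
#' @examples
#' g <- spread_directions(16)
#' range(rowSums(g^2)) # all 1
spread_directions <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 6L) {
    phi <- (1 + sqrt(5)) / 2
    ico <- rbind(c(1, phi, 0), c(-1, phi, 0), c(0, 1, phi),
                 c(0, -1, phi), c(phi, 0, 1), c(phi, 0, -1))
    return(ico / sqrt(1 + phi^2))
  }
  if (n == 12L) return(.dirs12)
  if (n == 16L) return(.dirs16)
  i <- seq_len(n) - 1L
  z <- (2 * i + 1) / n - 1
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# 60-direction set used to average directional apparent kurtosis into MK.
mk_direction_set <- function() spread_directions(60L)

# Rotation matrix taking the z-axis onto unit vector v (Rodrigues form).
rotation_z_to <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  a <- c(z[2] * v[3] - z[3] * v[2],
         z[3] * v[1] - z[1] * v[3],
         z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(a^2))
  a <- a / s
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}
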