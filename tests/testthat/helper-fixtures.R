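# Uniform ion-count rasters with a single rectangular ROI, for exact checks.
uniform_roi_images <- function(c12 = 99, c13 = 1, c15 = 0, size = 16,
                               roi = 3:10) {
  labels <- matrix(0L, size, size)
  labels[roi, roi] <- 1L
  imgs <- list(c12n14 = matrix(0, size, size),
               c13n14 = matrix(0, size, size),
               c12n15 = matrix(0, size, size))
  imgs$c12n14[roi, roi] <- c12
  imgs$c13n14[roi, roi] <- c13
  imgs$c12n15[roi, roi] <- c15
  list(images = imgs, labels = labels)
}

# Brute-force Kruskal-Wallis H with tie correction, straight from the rank
# definition; the independent oracle for compare_groups().
brute_force_H <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
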