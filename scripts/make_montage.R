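# Regenerates inst/extdata/montage128.csv, the schematic 128-channel layout
# shipped with the package. Deterministic; run from the repository root.
#
# Layout: concentric rings on the unit disc (front of head = +y). The F3/F4
# analysis clusters are the 7 channels nearest the canonical left/right
# frontal positions; by symmetry of the layout the two clusters are disjoint
# and mirror images of each other.

ring_n <- c(1L, 6L, 12L, 18L, 24L, 30L, 37L)   # sums to 128
ring_r <- c(0, 0.15, 0.30, 0.45, 0.60, 0.75, 0.90)

x <- numeric(0); y <- numeric(0)
for (k in seq_along(ring_n)) {
  m <- ring_n[k]
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  x <- c(x, ring_r[k] * sin(ang))
  y <- c(y, ring_r[k] * cos(ang))
}
n <- length(x)
stopifnot(n == 128L)
label <- sprintf("E%d", seq_len(n))

f3 <- c(-0.35, 0.45)   # left frontal
f4 <- c(+0.35, 0.45)   # right frontal
d3 <- sqrt((x - f3[1])^2 + (y - f3[2])^2)
d4 <- sqrt((x - f4[1])^2 + (y - f4[2])^2)
left  <- order(d3)[1:7]
right <- order(d4)[1:7]
stopifnot(length(intersect(left, right)) == 0L)

cluster <- rep("", n)
cluster[left]  <- "L"
cluster[right] <- "R"

out <- data.frame(label = label,
                  x = round(x, 6), y = round(y, 6),
                  cluster = cluster,
                  stringsAsFactors = FALSE)
write.csv(out, "inst/extdata/montage128.csv", row.names = FALSE, quote = FALSE)
cat("wrote inst/extdata/montage128.csv:", n, "channels;",
    "L cluster:", paste(label[left], collapse = " "), ";",
    "R cluster:", paste(label[right], collapse = " "), "\n")
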