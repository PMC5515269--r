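# Independent plain-R oracle for 3-D connected components: breadth-first
# flood fill over voxel coordinates, no shared code with the package's
# labeling routine.

flood_fill_oracle <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, dims)
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      idx <- queue[1]; queue <- queue[-1]
      z <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
      rem <- (idx - 1L) %% (dims[1] * dims[2])
      y <- rem %/% dims[1] + 1L
      x <- rem %% dims[1] + 1L
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs$dx[k]; yy <- y + offs$dy[k]; zz <- z + offs$dz[k]
        if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
            zz < 1 || zz > dims[3]) next
        j <- xx + dims[1] * (yy - 1L) + dims[1] * dims[2] * (zz - 1L)
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- current
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# component size multiset of an oracle labeling
oracle_sizes <- function(labels) sort(tabulate(labels[labels > 0]))
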