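# in-code fixtures shared across the test files

img8 <- function(m) gray_image(m, bit_depth = 8L)

const_img <- function(value, h = 64L, w = 64L, bits = 8L) {
  gray_image(matrix(value, h, w), bit_depth = bits)
}

# bright axis-aligned square on a dark background
square_img <- function(size = 100L, lo = 20L, hi = 220L, from = 41L, to = 60L) {
  m <- matrix(lo, size, size)
  m[from:to, from:to] <- hi
  img8(m)
}

# one right-angle corner: a bright quadrant meeting at (corner_row, corner_col)
corner_img <- function(size = 64L, corner = 31L, lo = 20L, hi = 220L) {
  m <- matrix(lo, size, size)
  m[1:corner, 1:corner] <- hi
  img8(m)
}

random_img <- function(h = 64L, w = 64L, bits = 8L, seed = 1L) {
  set.seed(seed)
  gray_image(matrix(sample.int(2^bits, h * w, replace = TRUE) - 1L, h, w),
             bit_depth = bits)
}

small_phantom <- function(seed = 1L, size = 192L) {
  generate_head_phantom(phantom_spec(size = size, n_structures = 30L,
                                     seed = seed))
}
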