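# Minimal 16-bit grayscale PNG encoder. The png package reads 16-bit
# images but only writes 8-bit; quantitative intensity images need the
# full stored range, so deep images are written here (IHDR bit depth 16,
# colour type 0, no filtering; IDAT is a zlib stream from memCompress).
# CRC32 is carried as a double in [0, 2^32) since R has no unsigned ints.

# xor of two nonnegative doubles < 2^32, byte-wise
xor32 <- function(a, b) {
  r <- 0; m <- 1
  for (i in 1:4) {
    r <- r + bitwXor(as.integer(a %% 256), as.integer(b %% 256)) * m
    a <- a %/% 256; b <- b %/% 256; m <- m * 256
  }
  r
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwXor(as.integer(c %% 256), b) + 1L
    c <- xor32(c %/% 256, tab[idx])
  }
  xor32(c, 4294967295)
}

u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

write_png16 <- function(image, path) {
  px <- pmin(pmax(round(image), 0), 65535)
  h <- nrow(px); w <- ncol(px)
  # scanlines: filter byte 0 then big-endian 16-bit samples, row-major
  t_px <- t(px)
  raw_rows <- lapply(seq_len(h), function(r) {
    v <- as.integer(t_px[, r])
    smp <- rbind(v %/% 256L, v %% 256L)
    c(as.raw(0), as.raw(as.vector(smp)))
  })
  idat <- memCompress(do.call(c, raw_rows), type = "gzip")  # zlib stream
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
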