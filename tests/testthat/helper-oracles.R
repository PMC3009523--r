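## independent brute-force oracles kept free of package internals

## direct evaluation of X[k] = sum_n x[n] exp(-i 2 pi k n / N)
naiveDFT <- function(x, k) {
    n <- length(x)
    idx <- 0:(n - 1)
    sum(complex(real = x, imaginary = 0) *
        (cos(2 * pi * k * idx / n) - 1i * sin(2 * pi * k * idx / n)))
}

randomDnaString <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## orthonormal Haar analysis matrix for one level on an even length:
## independent route to the butterfly implementation
haarMatrix1 <- function(n) {
    stopifnot(n %% 2 == 0)
    m <- matrix(0, n, n)
    for (i in seq_len(n / 2)) {
        m[i, 2 * i - 1] <- 1 / sqrt(2)          # approximation rows
        m[i, 2 * i] <- 1 / sqrt(2)
        m[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2)  # detail rows
        m[n / 2 + i, 2 * i] <- -1 / sqrt(2)
    }
    m
}

## reference magnitude response from the coefficient vectors alone
naiveMagnitude <- function(b, a, omega) {
    num <- vapply(omega, function(w)
        sum(b * exp(-1i * w * (seq_along(b) - 1))), complex(1))
    den <- vapply(omega, function(w)
        sum(a * exp(-1i * w * (seq_along(a) - 1))), complex(1))
    Mod(num / den)
}

makePowerTrack <- function(values, origin = 1L, record = "toy") {
    new("PowerTrack", values = as.numeric(values), method = "toy",
        recordId = record, originOffset = as.integer(origin),
        transientLength = 0L)
}
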