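# Independent oracles used to cross-check the implementation. These read
# the same plain-text mass asset as the package but compute everything by
# per-residue loops, kept deliberately separate from the package's code
# paths.

.oracleMassTab <- local({
    path <- system.file("extdata", "monoisotopic_masses.csv",
        package = "mrmquant", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
})

oracleConstant <- function(name) {
    .oracleMassTab$mass_da[.oracleMassTab$type == "constant" &
        .oracleMassTab$name == name]
}

oracleResidueMass <- function(ch) {
    .oracleMassTab$mass_da[.oracleMassTab$type == "residue" &
        .oracleMassTab$name == ch]
}

# residue-by-residue mass summation
oracleMass <- function(sequence, heavy = FALSE, cam = TRUE) {
    chars <- strsplit(sequence, "")[[1]]
    m <- oracleConstant("water")
    for (ch in chars) {
        m <- m + oracleResidueMass(ch)
        if (cam && ch == "C") {
            m <- m + .oracleMassTab$mass_da[.oracleMassTab$type ==
                "modification"]
        }
    }
    if (heavy) {
        cterm <- chars[length(chars)]
        m <- m + .oracleMassTab$mass_da[.oracleMassTab$type ==
            "label_shift" & .oracleMassTab$name == cterm]
    }
    m
}

oracleFragmentMz <- function(sequence, ion, index, charge = 1,
                             heavy = FALSE) {
    chars <- strsplit(sequence, "")[[1]]
    n <- length(chars)
    piece <- if (ion == "y") chars[(n - index + 1):n] else chars[1:index]
    m <- 0
    for (ch in piece) {
        m <- m + oracleResidueMass(ch)
        if (ch == "C") {
            m <- m + .oracleMassTab$mass_da[.oracleMassTab$type ==
                "modification"]
        }
    }
    if (ion == "y") {
        m <- m + oracleConstant("water")
        if (heavy) {
            m <- m + .oracleMassTab$mass_da[.oracleMassTab$type ==
                "label_shift" & .oracleMassTab$name == chars[n]]
        }
    }
    (m + charge * oracleConstant("proton")) / charge
}

# brute-force cleavage: walk every position and apply the rule textually
oracleDigest <- function(sequence, enzyme) {
    chars <- strsplit(sequence, "")[[1]]
    frags <- character(0)
    cur <- ""
    for (i in seq_along(chars)) {
        cur <- paste0(cur, chars[i])
        nxt <- if (i < length(chars)) chars[i + 1] else ""
        cutHere <- switch(enzyme,
            trypsin = chars[i] %in% c("K", "R") && nxt != "P" && nxt != "",
            lysc = chars[i] == "K" && nxt != "",
            lysc_then_trypsin = (chars[i] == "K" ||
                (chars[i] == "R" && nxt != "P")) && nxt != ""
        )
        if (cutHere) {
            frags <- c(frags, cur)
            cur <- ""
        }
    }
    c(frags, cur)
}

randomSequence <- function(len) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
        replace = TRUE), collapse = "")
}

# random tryptic-looking peptide: no internal cleavage site, K/R terminus
randomPeptide <- function(len = 10) {
    body <- sample(setdiff(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], "P"),
        len - 1, replace = TRUE)
    paste(c(body, sample(c("K", "R"), 1)), collapse = "")
}
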