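## Deterministic constructors for hand-built read pairs.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

## build a clean (error-free) read pair from a molecule: each read is
## molecule strand + adaptor + random padding, truncated to read_len
make_clean_pair <- function(molecule, read_len,
                            adaptors = adaptor_pair(), q = 40,
                            id = "pair") {
  template <- function(strand, adaptor) {
    t <- substr(strand, 1, read_len)
    if (nchar(t) < read_len) t <- substr(paste0(t, adaptor), 1, read_len)
    if (nchar(t) < read_len) {
      t <- paste0(t, rand_seq(read_len - nchar(t)))
    }
    t
  }
  t1 <- template(molecule, adaptors$a1)
  t2 <- template(oracle_revcomp(molecule), adaptors$a2)
  list(r1 = read_record(id, t1, rep(q, nchar(t1))),
       r2 = read_record(id, t2, rep(q, nchar(t2))))
}

## a fully random read pair (no shared molecule) with random qualities
make_random_pair <- function(len1, len2, qmin = 2, qmax = 40,
                             id = "rnd") {
  list(r1 = read_record(id, rand_seq(len1),
                        sample(qmin:qmax, len1, replace = TRUE)),
       r2 = read_record(id, rand_seq(len2),
                        sample(qmin:qmax, len2, replace = TRUE)))
}
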