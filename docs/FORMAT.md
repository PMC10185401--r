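# BUSZ on-disk layout (as written by buszr)

All fixed-width integers are little-endian. All bit streams are MSB-first
within each byte. This document is normative for this implementation; other
BUSZ writers may lay out their payloads differently at the bit level.

## Plain BUS file

```
magic    4 bytes   "BUS\0"
version  u32
bc_len   u32       barcode length in nucleotides, 1..32
umi_len  u32       UMI length in nucleotides, 1..32
t_len    u32       length of the free text that follows
text     t_len bytes
records  n x 32 bytes
```

Each record (32 bytes):

```
barcode  u64   2-bit encoded (A=00, C=01, G=10, T=11, leftmost base most
               significant)
umi      u64   2-bit encoded
ec       i32   equivalence-class id
count    u32
flags    u32
padding  u32   written as zero
```

## BUSZ file

```
magic       8 bytes  "BUSZ0001"
version     u32   \
bc_len      u32    | copied from the input BUS header
umi_len     u32    |
t_len, text        /
block_size  u32   records per block (default 10000)
n_pfd       u32   NewPFD sub-block size (default 512)
f_ppt       u32   NewPFD fraction in parts per thousand (default 900);
                  informational at decode time (b, k and the exception
                  lists are explicit in the payload)
blocks      data blocks, see below
terminator  u32 0, u32 0
```

Each data block:

```
n_records  u32   1..block_size (short blocks only at end of file)
n_bytes    u32   compressed payload size in bytes
payload    n_bytes
```

The payload is the concatenation of five independently compressed,
byte-aligned column payloads, in the order barcode, UMI, EC, count, flags
(the padding column is not stored). Each column payload is prefixed with a
u32 byte count so that columns are independently skippable:

```
len_1 u32, bytes_1, len_2 u32, bytes_2, ..., len_5 u32, bytes_5
```

### Fibonacci code

Positive integers only. The Zeckendorf representation over F1=1, F2=2,
F3=3, F4=5, ... is emitted lowest index first, followed by an extra 1 bit:
every codeword ends "11" and contains no other adjacent pair of 1 bits.
Values up to 2^64 are representable.

### Column codecs

* **barcode** — deltas of adjacent barcodes (non-negative because the file
  is sorted); the first barcode of the block is stored raw (a delta from
  an implicit 0) so blocks decompress independently. The delta list is
  FRLE0-coded: a maximal run of L zeros becomes fib(1) fib(L); any other
  value v becomes fib(v+1).
* **UMI** — deltas only between adjacent records of the same barcode; at a
  barcode change (and for the block's first record) the raw UMI value is
  used. FRLE0-coded.
* **EC** — NewPFD over sub-blocks of n_pfd consecutive values:
  * k = minimum of the sub-block; offsets are x - k.
  * b = bit width of the ceil(f * m)-th smallest offset, where m is the
    actual sub-block length (the last sub-block may be short); b is
    capped at 32. Offsets needing more than b bits are exceptions
    (their high bits may still be coded even when the computed width
    exceeded the cap, preserving losslessness for arbitrary input).
  * layout: fib(b+1) fib(k+1) fib(E+1), then per exception (ascending
    position p_i, 0-based, p_0 = -1) the pair
    fib(p_i - p_(i-1) - 1 + 1) fib(offset >> b), then m fixed-width
    b-bit slots holding offset mod 2^b.
* **count** — FRLE1 (values are strictly positive): a run of L ones
  becomes fib(1) fib(L); any other value v becomes fib(v).
* **flags** — FRLE0.

Each column's bit stream is zero-padded to a byte boundary.

## Index file (optional, suffix ".idx")

```
magic    8 bytes  "BUSZIDX1"
entries  per data block: first_barcode u64, n_bytes u64
```

Entries are fixed-width; block offsets are reconstructed as cumulative
sums of (8 + n_bytes) starting after the BUSZ header. A reader verifies
that the reconstructed total matches the file size and that each candidate
block's header agrees with its index entry.
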