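#include "busz_core.h"

#include <algorithm>
#include <cmath>
#include <cstring>

namespace busz {

// ---------------------------------------------------------------- bitstream

void BitWriter::writeBit(unsigned b) {
  const uint64_t byteIdx = nbits >> 3;
  if (byteIdx >= bytes.size()) bytes.push_back(0);
  if (b) bytes[byteIdx] |= static_cast<uint8_t>(0x80u >> (nbits & 7));
  ++nbits;
}

void BitWriter::writeBits(uint64_t value, unsigned width) {
  if (width > 64) throw busz_error("domain: bit width exceeds 64");
  if (width < 64 && width > 0 && (value >> width) != 0)
    throw busz_error("domain: value does not fit in the given bit width");
  if (width == 0) {
    if (value != 0)
      throw busz_error("domain: value does not fit in the given bit width");
    return;
  }
  for (unsigned i = width; i-- > 0;) writeBit((value >> i) & 1u);
}

void BitWriter::alignToByte() {
  while (nbits & 7) writeBit(0);
}

unsigned BitReader::readBit() {
  if (pos_ >= nbits_) throw busz_error("truncated: bit stream exhausted");
  const unsigned b = (data_[pos_ >> 3] >> (7 - (pos_ & 7))) & 1u;
  ++pos_;
  return b;
}

uint64_t BitReader::readBits(unsigned width) {
  if (width > 64) throw busz_error("domain: bit width exceeds 64");
  if (width == 0) return 0;
  if (pos_ + width > nbits_)
    throw busz_error("truncated: bit stream exhausted");
  uint64_t v = 0;
  for (unsigned i = 0; i < width; ++i) v = (v << 1) | readBit();
  return v;
}

void BitReader::alignToByte() {
  while (pos_ & 7) {
    if (pos_ >= nbits_) return;
    ++pos_;
  }
}

// ---------------------------------------------------------------- fibonacci

// F1=1, F2=2, ...; table extends past 2^64 so any value <= 2^64 is covered.
static const std::vector<u128>& fibTable() {
  static std::vector<u128> F = [] {
    std::vector<u128> t;
    t.push_back(1);
    t.push_back(2);
    const u128 lim = (u128)1 << 66;
    while (t.back() < lim) t.push_back(t[t.size() - 1] + t[t.size() - 2]);
    return t;
  }();
  return F;
}

void fibEncode(u128 n, BitWriter& bw) {
  if (n == 0) throw busz_error("domain: Fibonacci coding requires n >= 1");
  const std::vector<u128>& F = fibTable();
  if (n > ((u128)1 << 64))
    throw busz_error("domain: value too large for Fibonacci coding");
  // greedy Zeckendorf, highest term first
  size_t hi = 0;
  while (hi + 1 < F.size() && F[hi + 1] <= n) ++hi;
  std::vector<uint8_t> bits(hi + 1, 0);
  u128 rem = n;
  for (size_t i = hi + 1; i-- > 0;) {
    if (F[i] <= rem) {
      bits[i] = 1;
      rem -= F[i];
    }
  }
  for (size_t i = 0; i <= hi; ++i) bw.writeBit(bits[i]);
  bw.writeBit(1);  // terminator: codeword ends "11"
}

u128 fibDecode(BitReader& br) {
  const std::vector<u128>& F = fibTable();
  u128 v = 0;
  unsigned prev = 0;
  for (size_t i = 0;; ++i) {
    const unsigned b = br.readBit();
    if (b && prev) return v;
    if (b) {
      if (i >= F.size())
        throw busz_error("corruption: Fibonacci codeword out of range");
      v += F[i];
      if (v > ((u128)1 << 64))
        throw busz_error("corruption: Fibonacci codeword out of range");
    }
    prev = b;
  }
}

static uint64_t fibDecodeU64(BitReader& br) {
  const u128 v = fibDecode(br);
  if (v > (u128)UINT64_MAX)
    throw busz_error("corruption: decoded value exceeds 64 bits");
  return (uint64_t)v;
}

// ------------------------------------------------------------------- FRLE

void frle0Encode(const std::vector<uint64_t>& v, BitWriter& bw) {
  size_t i = 0;
  const size_t n = v.size();
  while (i < n) {
    if (v[i] == 0) {
      size_t j = i;
      while (j < n && v[j] == 0) ++j;
      fibEncode(1, bw);                 // run marker: fib(0 + 1)
      fibEncode((u128)(j - i), bw);     // run length, >= 1, no increment
      i = j;
    } else {
      fibEncode((u128)v[i] + 1, bw);    // literal, +1 (values may be zero)
      ++i;
    }
  }
}

std::vector<uint64_t> frle0Decode(BitReader& br, uint64_t n) {
  std::vector<uint64_t> out;
  out.reserve(n);
  while (out.size() < n) {
    const u128 c = fibDecode(br);
    if (c == 1) {
      const uint64_t len = fibDecodeU64(br);
      if (out.size() + len > n)
        throw busz_error("corruption: zero run overflows expected count");
      out.insert(out.end(), len, 0);
    } else {
      out.push_back((uint64_t)(c - 1));
    }
  }
  return out;
}

void frle1Encode(const std::vector<uint64_t>& v, BitWriter& bw) {
  size_t i = 0;
  const size_t n = v.size();
  while (i < n) {
    if (v[i] == 0)
      throw busz_error("domain: FRLE1 requires strictly positive values");
    if (v[i] == 1) {
      size_t j = i;
      while (j < n && v[j] == 1) ++j;
      fibEncode(1, bw);                // run marker
      fibEncode((u128)(j - i), bw);    // run length
      i = j;
    } else {
      fibEncode((u128)v[i], bw);       // literal, no increment
      ++i;
    }
  }
}

std::vector<uint64_t> frle1Decode(BitReader& br, uint64_t n) {
  std::vector<uint64_t> out;
  out.reserve(n);
  while (out.size() < n) {
    const u128 c = fibDecode(br);
    if (c == 1) {
      const uint64_t len = fibDecodeU64(br);
      if (out.size() + len > n)
        throw busz_error("corruption: one run overflows expected count");
      out.insert(out.end(), len, 1);
    } else {
      out.push_back((uint64_t)c);
    }
  }
  return out;
}

// ------------------------------------------------------------------ deltas

std::vector<uint64_t> deltaBarcodes(const std::vector<uint64_t>& bc) {
  std::vector<uint64_t> out(bc.size());
  for (size_t i = 0; i < bc.size(); ++i) {
    if (i == 0) {
      out[0] = bc[0];  // block-local raw anchor (delta from implicit 0)
    } else {
      if (bc[i] < bc[i - 1])
        throw busz_error("not-sorted: barcode decreases at record " +
                         std::to_string(i + 1));
      out[i] = bc[i] - bc[i - 1];
    }
  }
  return out;
}

std::vector<uint64_t> undeltaBarcodes(const std::vector<uint64_t>& d) {
  std::vector<uint64_t> out(d.size());
  uint64_t acc = 0;
  for (size_t i = 0; i < d.size(); ++i) {
    acc += d[i];
    out[i] = acc;
  }
  return out;
}

std::vector<uint64_t> deltaUmis(const std::vector<uint64_t>& umi,
                                const std::vector<uint64_t>& bc) {
  if (umi.size() != bc.size())
    throw busz_error("domain: UMI and barcode vectors differ in length");
  std::vector<uint64_t> out(umi.size());
  for (size_t i = 0; i < umi.size(); ++i) {
    if (i > 0 && bc[i] == bc[i - 1]) {
      if (umi[i] < umi[i - 1])
        throw busz_error("not-sorted: UMI decreases within barcode at record " +
                         std::to_string(i + 1));
      out[i] = umi[i] - umi[i - 1];
    } else {
      out[i] = umi[i];  // barcode change (or first record): raw value
    }
  }
  return out;
}

std::vector<uint64_t> undeltaUmis(const std::vector<uint64_t>& d,
                                  const std::vector<uint64_t>& bc) {
  if (d.size() != bc.size())
    throw busz_error("domain: delta and barcode vectors differ in length");
  std::vector<uint64_t> out(d.size());
  for (size_t i = 0; i < d.size(); ++i) {
    if (i > 0 && bc[i] == bc[i - 1])
      out[i] = out[i - 1] + d[i];
    else
      out[i] = d[i];
  }
  return out;
}

// ------------------------------------------------------------------ NewPFD

static unsigned bitWidth(uint64_t x) {
  return x == 0 ? 0 : 64 - __builtin_clzll(x);
}

void newpfdEncode(const std::vector<uint64_t>& v, uint64_t nPfd, double f,
                  BitWriter& bw, std::vector<NewpfdSubblock>* plan) {
  if (nPfd < 1) throw busz_error("domain: NewPFD sub-block size must be >= 1");
  if (!(f > 0.0) || f > 1.0)
    throw busz_error("domain: NewPFD fraction must be in (0, 1]");
  for (size_t start = 0; start < v.size(); start += nPfd) {
    const size_t m = std::min<size_t>(nPfd, v.size() - start);
    uint64_t k = v[start];
    for (size_t i = 1; i < m; ++i) k = std::min(k, v[start + i]);
    std::vector<uint64_t> off(m);
    for (size_t i = 0; i < m; ++i) off[i] = v[start + i] - k;
    // minimal b such that >= ceil(f*m) offsets fit in b bits: the bit width
    // of the ceil(f*m)-th smallest offset.  Rank uses the actual (possibly
    // short, final) sub-block length.  b is capped at 32.
    std::vector<uint64_t> sorted(off);
    std::sort(sorted.begin(), sorted.end());
    const size_t rank = (size_t)std::min<double>(
        (double)m, std::ceil(f * (double)m));
    unsigned b = bitWidth(sorted[rank == 0 ? 0 : rank - 1]);
    if (b > 32) b = 32;

    std::vector<size_t> excPos;
    for (size_t i = 0; i < m; ++i)
      if (b < 64 && (off[i] >> b) != 0) excPos.push_back(i);

    fibEncode((u128)b + 1, bw);
    fibEncode((u128)k + 1, bw);
    fibEncode((u128)excPos.size() + 1, bw);
    // interleaved (position gap, high bits) per exception; gaps are
    // d = p_i - p_{i-1} - 1 with p_0 = -1, stored as fib(d + 1)
    size_t prev = (size_t)-1;
    for (size_t p : excPos) {
      fibEncode((u128)(p - prev - 1) + 1, bw);
      fibEncode((u128)(off[p] >> b), bw);  // >= 1 by construction
      prev = p;
    }
    const uint64_t mask = b == 64 ? UINT64_MAX : (((uint64_t)1 << b) - 1);
    for (size_t i = 0; i < m; ++i) bw.writeBits(off[i] & mask, b);

    if (plan) plan->push_back({k, b, (uint64_t)m, (uint64_t)excPos.size()});
  }
}

std::vector<uint64_t> newpfdDecode(BitReader& br, uint64_t n, uint64_t nPfd) {
  if (nPfd < 1) throw busz_error("domain: NewPFD sub-block size must be >= 1");
  std::vector<uint64_t> out;
  out.reserve(n);
  while (out.size() < n) {
    const uint64_t m = std::min<uint64_t>(nPfd, n - out.size());
    const uint64_t b64 = fibDecodeU64(br) - 1;
    if (b64 > 32) throw busz_error("corruption: NewPFD slot width exceeds 32");
    const unsigned b = (unsigned)b64;
    const uint64_t k = fibDecodeU64(br) - 1;
    const uint64_t nExc = fibDecodeU64(br) - 1;
    if (nExc > m)
      throw busz_error("corruption: NewPFD exception count exceeds sub-block");
    std::vector<uint64_t> excPos(nExc), excHigh(nExc);
    uint64_t prev = UINT64_MAX;  // acts as -1
    for (uint64_t e = 0; e < nExc; ++e) {
      const uint64_t gap = fibDecodeU64(br) - 1;
      const uint64_t p = prev + 1 + gap;  // wraps correctly from -1
      if (p >= m)
        throw busz_error("corruption: NewPFD exception position beyond sub-block");
      excPos[e] = p;
      excHigh[e] = fibDecodeU64(br);
      prev = p;
    }
    std::vector<uint64_t> vals(m);
    for (uint64_t i = 0; i < m; ++i) vals[i] = k + br.readBits(b);
    for (uint64_t e = 0; e < nExc; ++e)
      vals[excPos[e]] += excHigh[e] << b;
    out.insert(out.end(), vals.begin(), vals.end());
  }
  return out;
}

// --------------------------------------------------------------- sequences

uint64_t encodeSeq(const std::string& s) {
  if (s.empty()) throw busz_error("domain: empty nucleotide sequence");
  if (s.size() > 32)
    throw busz_error("domain: nucleotide sequence longer than 32");
  uint64_t code = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    unsigned v;
    switch (s[i]) {
      case 'A': case 'a': v = 0; break;
      case 'C': case 'c': v = 1; break;
      case 'G': case 'g': v = 2; break;
      case 'T': case 't': v = 3; break;
      default:
        throw busz_error("domain: invalid nucleotide '" +
                         std::string(1, s[i]) + "' at position " +
                         std::to_string(i + 1));
    }
    code = (code << 2) | v;
  }
  return code;
}

std::string decodeSeq(uint64_t code, unsigned len) {
  if (len < 1 || len > 32)
    throw busz_error("domain: sequence length must be in 1..32");
  if (len < 32 && (code >> (2 * len)) != 0)
    throw busz_error("domain: code out of range for sequence length");
  static const char* alpha = "ACGT";
  std::string s(len, 'A');
  for (unsigned i = 0; i < len; ++i)
    s[i] = alpha[(code >> (2 * (len - 1 - i))) & 3u];
  return s;
}

// ------------------------------------------------------------------- block

// Block payload: five byte-aligned column payloads (barcode, UMI, EC, count,
// flags), each prefixed with a little-endian u32 byte count.
static void putU32(std::vector<uint8_t>& out, uint32_t v) {
  out.push_back(v & 0xff);
  out.push_back((v >> 8) & 0xff);
  out.push_back((v >> 16) & 0xff);
  out.push_back((v >> 24) & 0xff);
}

static void appendColumn(std::vector<uint8_t>& out, BitWriter& bw) {
  bw.alignToByte();
  if (bw.bytes.size() > UINT32_MAX)
    throw busz_error("domain: column payload exceeds 4 GiB");
  putU32(out, (uint32_t)bw.bytes.size());
  out.insert(out.end(), bw.bytes.begin(), bw.bytes.end());
}

std::vector<uint8_t> compressBlock(const std::vector<BusRecord>& recs,
                                   const BuszParams& p) {
  const size_t n = recs.size();
  if (n == 0) throw busz_error("domain: cannot compress an empty block");
  std::vector<uint64_t> bc(n), umi(n), ec(n), cnt(n), flg(n);
  for (size_t i = 0; i < n; ++i) {
    if (recs[i].ec < 0)
      throw busz_error("domain: negative EC at record " + std::to_string(i + 1));
    if (recs[i].count == 0)
      throw busz_error("domain: zero count at record " + std::to_string(i + 1));
    bc[i] = recs[i].barcode;
    umi[i] = recs[i].umi;
    ec[i] = (uint64_t)recs[i].ec;
    cnt[i] = recs[i].count;
    flg[i] = recs[i].flags;
  }
  // sortedness within the block (file-level check covers boundaries)
  for (size_t i = 1; i < n; ++i) {
    const BusRecord &a = recs[i - 1], &b = recs[i];
    if (b.barcode < a.barcode ||
        (b.barcode == a.barcode &&
         (b.umi < a.umi || (b.umi == a.umi && b.ec < a.ec))))
      throw busz_error("not-sorted: record " + std::to_string(i + 1) +
                       " is out of order within the block");
  }

  std::vector<uint8_t> out;
  BitWriter w1, w2, w3, w4, w5;
  frle0Encode(deltaBarcodes(bc), w1);
  appendColumn(out, w1);
  frle0Encode(deltaUmis(umi, bc), w2);
  appendColumn(out, w2);
  newpfdEncode(ec, p.nPfd, p.f, w3);
  appendColumn(out, w3);
  frle1Encode(cnt, w4);
  appendColumn(out, w4);
  frle0Encode(flg, w5);
  appendColumn(out, w5);
  return out;
}

static uint32_t getU32(const std::vector<uint8_t>& in, size_t& at) {
  if (at + 4 > in.size())
    throw busz_error("corruption: block payload truncated");
  uint32_t v = (uint32_t)in[at] | ((uint32_t)in[at + 1] << 8) |
               ((uint32_t)in[at + 2] << 16) | ((uint32_t)in[at + 3] << 24);
  at += 4;
  return v;
}

std::vector<BusRecord> decompressBlock(const std::vector<uint8_t>& payload,
                                       uint64_t n, const BuszParams& p) {
  if (n == 0) throw busz_error("domain: block record count must be >= 1");
  size_t at = 0;
  std::vector<std::vector<uint64_t>> cols(5);
  std::vector<uint64_t> bc;
  for (int c = 0; c < 5; ++c) {
    const uint32_t len = getU32(payload, at);
    if (at + len > payload.size())
      throw busz_error("corruption: column payload truncated");
    BitReader br(payload.data() + at, (uint64_t)len * 8);
    switch (c) {
      case 0: bc = undeltaBarcodes(frle0Decode(br, n)); break;
      case 1: cols[1] = undeltaUmis(frle0Decode(br, n), bc); break;
      case 2: cols[2] = newpfdDecode(br, n, p.nPfd); break;
      case 3: cols[3] = frle1Decode(br, n); break;
      case 4: cols[4] = frle0Decode(br, n); break;
    }
    at += len;
  }
  if (at != payload.size())
    throw busz_error("corruption: trailing bytes after block columns");
  std::vector<BusRecord> recs(n);
  for (uint64_t i = 0; i < n; ++i) {
    if (cols[2][i] > (uint64_t)INT32_MAX)
      throw busz_error("corruption: decoded EC exceeds 32-bit signed range");
    if (cols[3][i] > UINT32_MAX || cols[4][i] > UINT32_MAX)
      throw busz_error("corruption: decoded count/flags exceed 32-bit range");
    recs[i] = {bc[i], cols[1][i], (int32_t)cols[2][i], (uint32_t)cols[3][i],
               (uint32_t)cols[4][i]};
  }
  return recs;
}

}  // namespace busz
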