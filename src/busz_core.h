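#ifndef BUSZR_CORE_H
#define BUSZR_CORE_H

#include <cstdint>
#include <cstddef>
#include <string>
#include <vector>
#include <stdexcept>

namespace busz {

typedef unsigned __int128 u128;

// Error taxonomy: message prefixes are mapped to R condition classes
// ("format:", "corruption:", "truncated:", "not-sorted:", "domain:",
// "integrity:", "io:").
struct busz_error : std::runtime_error {
  explicit busz_error(const std::string& msg) : std::runtime_error(msg) {}
};

// ---------------------------------------------------------------- bitstream
// MSB-first within each byte, for both fixed-width slots and Fibonacci
// codewords. Unwritten trailing bits of the last byte are zero.
class BitWriter {
public:
  std::vector<uint8_t> bytes;
  uint64_t nbits = 0;
  void writeBit(unsigned b);
  void writeBits(uint64_t value, unsigned width);  // MSB first, width <= 64
  void alignToByte();                              // zero padding
};

class BitReader {
public:
  BitReader(const uint8_t* data, uint64_t nbits)
      : data_(data), nbits_(nbits), pos_(0) {}
  unsigned readBit();
  uint64_t readBits(unsigned width);
  void alignToByte();
  uint64_t pos() const { return pos_; }
  uint64_t remaining() const { return nbits_ - pos_; }

private:
  const uint8_t* data_;
  uint64_t nbits_;
  uint64_t pos_;
};

// ---------------------------------------------------------------- fibonacci
// Universal code over F1=1, F2=2, F3=3, F4=5, ... Zeckendorf bits emitted
// lowest index first, terminated by an extra 1 (every codeword ends "11").
// Values up to 2^64 are supported (callers encode v+1 for v up to 2^64-1).
void fibEncode(u128 n, BitWriter& bw);
u128 fibDecode(BitReader& br);

// ------------------------------------------------------------------- FRLE
// FRLE0: runs of zeros -> fib(1) marker + fib(run length); literals v >= 1
// -> fib(v+1). FRLE1: runs of ones -> fib(1) + fib(run length); literals
// v >= 2 -> fib(v); zeros are a domain error.
void frle0Encode(const std::vector<uint64_t>& v, BitWriter& bw);
std::vector<uint64_t> frle0Decode(BitReader& br, uint64_t n);
void frle1Encode(const std::vector<uint64_t>& v, BitWriter& bw);
std::vector<uint64_t> frle1Decode(BitReader& br, uint64_t n);

// ------------------------------------------------------------------ deltas
std::vector<uint64_t> deltaBarcodes(const std::vector<uint64_t>& bc);
std::vector<uint64_t> undeltaBarcodes(const std::vector<uint64_t>& d);
std::vector<uint64_t> deltaUmis(const std::vector<uint64_t>& umi,
                                const std::vector<uint64_t>& bc);
std::vector<uint64_t> undeltaUmis(const std::vector<uint64_t>& d,
                                  const std::vector<uint64_t>& bc);

// ------------------------------------------------------------------ NewPFD
struct NewpfdSubblock {      // per-sub-block plan, for audits/tests
  uint64_t k;
  unsigned b;
  uint64_t nValues;
  uint64_t nExceptions;
};
void newpfdEncode(const std::vector<uint64_t>& v, uint64_t nPfd, double f,
                  BitWriter& bw, std::vector<NewpfdSubblock>* plan = nullptr);
std::vector<uint64_t> newpfdDecode(BitReader& br, uint64_t n, uint64_t nPfd);

// --------------------------------------------------------------- sequences
uint64_t encodeSeq(const std::string& s);          // A=00 C=01 G=10 T=11
std::string decodeSeq(uint64_t code, unsigned len);

// ----------------------------------------------------------------- records
struct BusRecord {
  uint64_t barcode;
  uint64_t umi;
  int32_t ec;
  uint32_t count;
  uint32_t flags;
};

struct BusHeader {
  uint32_t version;
  uint32_t bcLen;
  uint32_t umiLen;
  std::string text;
};

struct BuszParams {
  uint64_t blockSize;  // records per block, default 10000
  uint64_t nPfd;       // NewPFD sub-block size, default 512
  double f;            // in-range fraction, default 0.9
};

// ------------------------------------------------------------------- block
std::vector<uint8_t> compressBlock(const std::vector<BusRecord>& recs,
                                   const BuszParams& p);
std::vector<BusRecord> decompressBlock(const std::vector<uint8_t>& payload,
                                       uint64_t n, const BuszParams& p);

}  // namespace busz

#endif
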