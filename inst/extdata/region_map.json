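{
  "assignment": {
    "12": "none",
    "13": "none",
    "14": "CA3a",
    "15": "CA3a",
    "16": "CA3b",
    "17": "CA3b",
    "21": "CA1",
    "22": "none",
    "23": "none",
    "24": "CA3a",
    "25": "CA3a",
    "26": "CA3b",
    "27": "CA3b",
    "28": "CA3c",
    "31": "CA1",
    "32": "CA1",
    "33": "none",
    "34": "none",
    "35": "none",
    "36": "none",
    "37": "CA3c",
    "38": "CA3c",
    "41": "CA1",
    "42": "CA1",
    "43": "none",
    "44": "DG",
    "45": "DG",
    "46": "DG",
    "47": "CA3c",
    "48": "none",
    "51": "CA1",
    "52": "CA1",
    "53": "none",
    "54": "DG",
    "55": "DG",
    "56": "DG",
    "57": "none",
    "58": "none",
    "61": "Sub",
    "62": "Sub",
    "63": "none",
    "64": "none",
    "65": "none",
    "66": "none",
    "67": "none",
    "68": "none",
    "71": "Sub",
    "72": "Sub",
    "73": "Sub",
    "74": "Sub",
    "75": "none",
    "76": "none",
    "77": "none",
    "78": "none",
    "82": "Sub",
    "83": "Sub",
    "84": "Sub",
    "85": "none",
    "86": "none",
    "87": "none"
  },
  "cell_layer_pairs": {
    "CA3": [
      "17",
      "27"
    ],
    "CA1": [
      "31",
      "41"
    ],
    "Sub": [
      "72",
      "82"
    ],
    "DG": [
      "44",
      "54"
    ]
  }
}
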