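{
  "type": "FeatureCollection",
  "note": "SYNTHETIC simplified rectangles for testing only - NOT real national borders. Real analyses must supply their own boundary GeoJSON.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "China"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[97.6, 21.0], [104.0, 21.0], [104.0, 29.0], [97.6, 29.0], [97.6, 21.0]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "Myanmar"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[94.0, 18.0], [97.6, 18.0], [97.6, 27.0], [94.0, 27.0], [94.0, 18.0]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "India"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[89.0, 24.5], [94.0, 24.5], [94.0, 29.0], [89.0, 29.0], [89.0, 24.5]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "Bangladesh"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[88.0, 20.0], [94.0, 20.0], [94.0, 24.5], [88.0, 24.5], [88.0, 20.0]]]
      }
    }
  ]
}
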