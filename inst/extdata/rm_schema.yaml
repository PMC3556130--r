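# Declarative subset of the openEHR Reference Model used to augment
# archetypes with implicit mandatory constraints and to type extract nodes.
#
# Keys per attribute: name, type (RM class or one of the eight primitive
# kinds), mandatory, multiple, deprecated, auto_fill, default.
# auto_fill marks mandatory structural/context attributes that are excluded
# from generated forms by default and filled with the documented default at
# export time rather than entered clinically.
version: openehr-rm-1.0.2-subset-1
classes:
  LOCATABLE:
    abstract: true
    attributes: []
  CONTENT_ITEM:
    parent: LOCATABLE
    abstract: true
    attributes: []
  ENTRY:
    parent: CONTENT_ITEM
    abstract: true
    attributes:
      - {name: language, type: String, mandatory: true, auto_fill: true, default: "en"}
      - {name: encoding, type: String, mandatory: true, auto_fill: true, default: "UTF-8"}
      - {name: subject, type: String, mandatory: true, auto_fill: true, default: "self"}
  COMPOSITION:
    parent: LOCATABLE
    attributes:
      - {name: language, type: String, mandatory: true, auto_fill: true, default: "en"}
      - {name: territory, type: String, mandatory: true, auto_fill: true, default: "AT"}
      - {name: category, type: String, mandatory: true, auto_fill: true, default: "event"}
      - {name: composer, type: String, mandatory: true, auto_fill: true, default: "unknown"}
      - {name: content, type: CONTENT_ITEM, mandatory: false, multiple: true}
  SECTION:
    parent: CONTENT_ITEM
    attributes:
      - {name: items, type: CONTENT_ITEM, mandatory: false, multiple: true}
  OBSERVATION:
    parent: ENTRY
    attributes:
      - {name: data, type: HISTORY, mandatory: true}
      - {name: state, type: HISTORY, mandatory: false}
      - {name: protocol, type: ITEM_STRUCTURE, mandatory: false}
  EVALUATION:
    parent: ENTRY
    attributes:
      - {name: data, type: ITEM_STRUCTURE, mandatory: true}
      - {name: protocol, type: ITEM_STRUCTURE, mandatory: false}
  INSTRUCTION:
    parent: ENTRY
    attributes:
      - {name: narrative, type: DV_TEXT, mandatory: true}
      - {name: activities, type: ACTIVITY, mandatory: false, multiple: true}
      - {name: protocol, type: ITEM_STRUCTURE, mandatory: false}
  ACTION:
    parent: ENTRY
    attributes:
      - {name: time, type: DV_DATE_TIME, mandatory: true}
      - {name: description, type: ITEM_STRUCTURE, mandatory: true}
      - {name: protocol, type: ITEM_STRUCTURE, mandatory: false}
  ACTIVITY:
    parent: LOCATABLE
    attributes:
      - {name: description, type: ITEM_STRUCTURE, mandatory: true}
      - {name: timing, type: String, mandatory: false}
  HISTORY:
    parent: LOCATABLE
    attributes:
      - {name: origin, type: DV_DATE_TIME, mandatory: true}
      - {name: period, type: DV_DURATION, mandatory: false}
      - {name: duration, type: DV_DURATION, mandatory: false}
      - {name: events, type: EVENT, mandatory: false, multiple: true}
      - {name: summary, type: ITEM_STRUCTURE, mandatory: false}
  EVENT:
    parent: LOCATABLE
    attributes:
      - {name: time, type: DV_DATE_TIME, mandatory: true}
      - {name: data, type: ITEM_STRUCTURE, mandatory: true}
      - {name: state, type: ITEM_STRUCTURE, mandatory: false}
  POINT_EVENT:
    parent: EVENT
    attributes: []
  ITEM_STRUCTURE:
    parent: LOCATABLE
    abstract: true
    attributes: []
  ITEM_TREE:
    parent: ITEM_STRUCTURE
    attributes:
      - {name: items, type: ITEM, mandatory: false, multiple: true}
  ITEM_LIST:
    parent: ITEM_STRUCTURE
    attributes:
      - {name: items, type: ELEMENT, mandatory: false, multiple: true}
  ITEM_SINGLE:
    parent: ITEM_STRUCTURE
    attributes:
      - {name: item, type: ELEMENT, mandatory: true}
  ITEM:
    parent: LOCATABLE
    abstract: true
    attributes: []
  CLUSTER:
    parent: ITEM
    attributes:
      - {name: items, type: ITEM, mandatory: true, multiple: true}
  ELEMENT:
    parent: ITEM
    attributes:
      - {name: value, type: DATA_VALUE, mandatory: false}
      - {name: null_flavour, type: DV_CODED_TEXT, mandatory: false}
  DATA_VALUE:
    abstract: true
    attributes: []
  DV_TEXT:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: String, mandatory: true}
  DV_CODED_TEXT:
    parent: DV_TEXT
    attributes:
      - {name: defining_code, type: String, mandatory: true}
  DV_QUANTITY:
    parent: DATA_VALUE
    attributes:
      - {name: magnitude, type: Real, mandatory: true}
      - {name: units, type: String, mandatory: true}
      - {name: precision, type: Integer, mandatory: false}
      - {name: property, type: String, mandatory: false, deprecated: true}
  DV_COUNT:
    parent: DATA_VALUE
    attributes:
      - {name: magnitude, type: Integer, mandatory: true}
  DV_PROPORTION:
    parent: DATA_VALUE
    attributes:
      - {name: numerator, type: Real, mandatory: true}
      - {name: denominator, type: Real, mandatory: true}
      - {name: type, type: Integer, mandatory: true, auto_fill: true, default: "0"}
  DV_ORDINAL:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Integer, mandatory: true}
      - {name: symbol, type: DV_CODED_TEXT, mandatory: false}
  DV_BOOLEAN:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Boolean, mandatory: true}
  DV_DATE:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Date, mandatory: true}
  DV_TIME:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Time, mandatory: true}
  DV_DATE_TIME:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Date_Time, mandatory: true}
  DV_DURATION:
    parent: DATA_VALUE
    attributes:
      - {name: value, type: Duration, mandatory: true}
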