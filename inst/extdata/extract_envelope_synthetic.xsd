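<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic schema for the generic extract envelope emitted by this
     package. It pins the envelope structure (extract / subject / time /
     chapter); the archetype-driven content below each chapter has no fixed
     element inventory and is skipped by the wildcard. Not an official openEHR
     schema. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="http://schemas.openehr.org/v1"
           xmlns:oe="http://schemas.openehr.org/v1"
           elementFormDefault="qualified">
  <xs:element name="extract">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="subject" type="xs:string" minOccurs="0"/>
        <xs:element name="time" type="xs:string" minOccurs="0"/>
        <xs:element name="chapter" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:any processContents="skip" minOccurs="1" maxOccurs="unbounded"/>
            </xs:sequence>
            <xs:attribute name="document_id" type="xs:string"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema_version" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
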